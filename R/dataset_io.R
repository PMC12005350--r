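#' Read and write datasets as CSV with a JSON metadata sidecar
#'
#' Datasets travel as long-format CSV (`time, observable, value`, plus the
#' train/validation `split` label) next to a `<path>.meta.json` sidecar
#' carrying the noise model, its parameters, and the seed, so a run can be
#' reconstructed from files alone.
#'
#' @param data A `ude_dataset` (see [observe()]).
#' @param path CSV file path; the sidecar is written at `paste0(path, ".meta.json")`.
#' @return `write_dataset()` returns `path` invisibly; `read_dataset()` a
#'   `ude_dataset`.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "ude_dataset"))
  long <- data.frame(
    time = rep(data$times, times = ncol(data$y)),
    observable = rep(data$observable_names, each = nrow(data$y)),
    value = as.vector(data$y),
    split = rep(data$split_mask, times = ncol(data$y))
  )
  write.csv(long, path, row.names = FALSE)
  meta <- list(
    observable_names = data$observable_names,
    noise_model = data$noise_model,
    noise_params = data$noise_params,
    seed = data$seed
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  obs <- meta$observable_names
  times <- sort(unique(long$time))
  y <- sapply(obs, function(o) {
    sub <- long[long$observable == o, ]
    sub$value[order(sub$time)]
  })
  first <- long[long$observable == obs[1], ]
  first <- first[order(first$time), ]
  structure(
    list(
      times = times, y = as.matrix(y), observable_names = obs,
      noise_model = meta$noise_model, noise_params = as.list(meta$noise_params),
      split_mask = first$split, seed = as.integer(meta$seed)
    ),
    class = "ude_dataset"
  )
}
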