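#' Percentile intervals for the interpretable parameters
#'
#' Equal-tailed intervals on the constrained scale (rates per day, noise in
#' observable units) for alpha, gamma, and the noise parameter, computed from
#' any collection of unconstrained draws.
#'
#' @param draws Matrix (n x n_params) or list of unconstrained parameter
#'   vectors.
#' @param model A [ude_model()].
#' @param level Interval level, e.g. 0.99.
#' @return Data frame `param, lower, median, upper, level`.
#' @export
parameter_intervals <- function(draws, model, level = 0.99) {
  if (is.list(draws)) draws <- do.call(rbind, draws)
  stopifnot(nrow(draws) >= 2, level > 0, level < 1)
  con <- t(apply(draws, 1, function(th) {
    cp <- constrain_params(th, model)
    c(alpha = cp$alpha, gamma = cp$gamma, noise = cp$noise)
  }))
  probs <- c((1 - level) / 2, 0.5, 1 - (1 - level) / 2)
  out <- t(apply(con, 2, quantile, probs = probs, names = FALSE))
  data.frame(param = rownames(out), lower = out[, 1], median = out[, 2],
             upper = out[, 3], level = level, row.names = NULL)
}

#' Score bands against the known truth
#'
#' For each state (including the unobserved S and E) and for the transmission
#' rate beta(t), reports the fraction of grid points at which the true value
#' lies inside the band, together with the mean band width. Coverage of the
#' noiseless truth should be read from epistemic bands; coverage of noisy
#' replicates from predictive bands.
#'
#' @param bands A `uq_bands` object.
#' @param truth A `trajectory` on the same time grid.
#' @param restrict_beta Also report beta coverage restricted to times where
#'   the true `I * S > 0.01 * N` (the regime where beta is identifiable).
#' @return A `coverage_report`: data frame `quantity, coverage, mean_width,
#'   n_points`, plus attributes `level` and `method`.
#' @export
trajectory_coverage <- function(bands, truth, restrict_beta = TRUE) {
  stopifnot(inherits(bands, "uq_bands"), inherits(truth, "trajectory"))
  if (length(bands$times) != length(truth$times) ||
      max(abs(bands$times - truth$times)) > 1e-8)
    stop("bands and truth are on different time grids")
  true_vals <- cbind(truth$states, beta = truth$beta_values)
  rows <- lapply(colnames(true_vals), function(q) {
    tv <- true_vals[, q]
    inside <- bands$lower[, q] <= tv & tv <= bands$upper[, q]
    data.frame(quantity = q, coverage = mean(inside),
               mean_width = mean(bands$upper[, q] - bands$lower[, q]),
               n_points = length(tv))
  })
  out <- do.call(rbind, rows)
  if (restrict_beta) {
    N <- sum(truth$states[1, ])
    sel <- truth$states[, "I"] * truth$states[, "S"] > 0.01 * N
    if (any(sel)) {
      tv <- true_vals[sel, "beta"]
      inside <- bands$lower[sel, "beta"] <= tv & tv <= bands$upper[sel, "beta"]
      out <- rbind(out, data.frame(
        quantity = "beta_identifiable", coverage = mean(inside),
        mean_width = mean(bands$upper[sel, "beta"] - bands$lower[sel, "beta"]),
        n_points = sum(sel)))
    }
  }
  structure(out, level = bands$level, method = bands$method,
            class = c("coverage_report", "data.frame"))
}

#' Probe generalization at an unseen initial condition
#'
#' Simulates the truth from `new_x0` with the scenario's true parameters and
#' true beta(t), rebuilds each draw's bands from the same initial condition,
#' and scores coverage there — an out-of-data-domain test of whether the
#' learned hybrid model transfers beyond the training trajectory.
#'
#' @param draws List of unconstrained parameter vectors (ensemble members,
#'   posterior or variational samples).
#' @param model A [ude_model()].
#' @param config The `scenario_config` of the data-generating process.
#' @param new_x0 Initial state to probe, e.g. `c(0.8, 0.1, 0.0, 0.1)`.
#' @param t_grid Output times (default: the scenario grid).
#' @param level Band level.
#' @param method Label for the report.
#' @return List with `truth` (trajectory from `new_x0`), `bands`, and
#'   `coverage` (a `coverage_report`).
#' @export
generalization_experiment <- function(draws, model, config,
                                      new_x0 = c(0.8, 0.1, 0.0, 0.1),
                                      t_grid = config$t_grid, level = 0.99,
                                      method = "ensemble") {
  new_cfg <- config
  new_cfg$x0 <- setNames(as.numeric(new_x0), c("S", "E", "I", "R"))
  new_cfg$t_grid <- t_grid
  new_cfg$n_obs <- length(t_grid)
  truth <- simulate_trajectory(new_cfg)
  bands <- trajectory_bands(draws, model, t_grid, x0 = new_cfg$x0,
                            level = level, method = method)
  list(truth = truth, bands = bands,
       coverage = trajectory_coverage(bands, truth))
}

#' Align coverage reports from several back-ends
#'
#' @param reports Named list of `coverage_report`s computed on the same
#'   scenario (names label the methods).
#' @param path Optional CSV path.
#' @return Data frame `method, quantity, coverage, mean_width, n_points, level`.
#' @export
method_comparison <- function(reports, path = NULL) {
  stopifnot(length(reports) >= 2)
  levels <- vapply(reports, function(r) attr(r, "level"), numeric(1))
  if (length(unique(levels)) != 1)
    stop("coverage reports use different band levels; compare like with like")
  nms <- names(reports) %||%
    vapply(reports, function(r) attr(r, "method"), character(1))
  out <- do.call(rbind, lapply(seq_along(reports), function(i) {
    cbind(method = nms[i], as.data.frame(reports[[i]]),
          level = levels[i])
  }))
  rownames(out) <- NULL
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}
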