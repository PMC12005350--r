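#' Pointwise percentile bands over parameter draws
#'
#' Shared band machinery of all three back-ends: every draw (ensemble member,
#' posterior sample, or variational sample) is simulated forward from `x0`,
#' and equal-tailed percentile bands at `(1-level)/2` and `1-(1-level)/2` are
#' taken pointwise across draws for the four states, the network rate
#' beta(t), and the observables `obs_I`, `obs_R`. Epistemic bands use the
#' mean trajectories; `include_noise = TRUE` additionally draws observation
#' noise per draw for the observables (posterior-predictive bands). Draws
#' whose simulation fails at this `x0` are skipped and counted.
#'
#' @param draws List of unconstrained parameter vectors.
#' @param model A [ude_model()].
#' @param t_grid Output times.
#' @param x0 Initial state.
#' @param level Nominal band level in (0, 1).
#' @param include_noise Convolve observables with observation noise?
#' @param seed Seed for noise draws.
#' @param method Label stored on the result (`"ensemble"`, `"mcmc"`, `"vi"`).
#' @return A `uq_bands` object: matrices `lower`, `median`, `upper`
#'   (rows = times, columns = `S,E,I,R,beta,obs_I,obs_R`), `times`, `level`,
#'   `include_noise`, `n_draws`, `n_skipped`, `method`.
#' @export
trajectory_bands <- function(draws, model, t_grid, x0 = model$x0, level = 0.99,
                             include_noise = FALSE, seed = 1L,
                             method = "ensemble") {
  stopifnot(length(draws) >= 1, level > 0, level < 1)
  n_t <- length(t_grid)
  quantities <- c("S", "E", "I", "R", "beta", "obs_I", "obs_R")
  sims <- vector("list", length(draws))
  n_skipped <- 0L
  noise_draws <- withr::with_seed(seed, {
    lapply(seq_along(draws), function(i) {
      if (!include_noise) return(NULL)
      # pre-draw so skipping a member does not shift others' noise
      list(u = matrix(rnorm(2 * n_t), n_t, 2), seed_i = sample.int(1e9, 1))
    })
  })
  for (i in seq_along(draws)) {
    fw <- solve_forward(draws[[i]], model, t_grid, x0 = x0)
    if (!fw$ok) { n_skipped <- n_skipped + 1L; next }
    obs <- fw$yhat
    if (include_noise) {
      cp <- constrain_params(draws[[i]], model)
      if (model$noise_model == "gaussian") {
        obs <- obs + cp$noise * noise_draws[[i]]$u
      } else {
        obs <- withr::with_seed(noise_draws[[i]]$seed_i,
          matrix(rnbinom(2 * n_t, size = cp$noise, mu = pmax(obs, 0)), n_t, 2))
      }
    }
    sims[[i]] <- cbind(fw$states, beta = fw$beta,
                       obs_I = obs[, 1], obs_R = obs[, 2])
  }
  sims <- Filter(Negate(is.null), sims)
  if (!length(sims)) stop("all draws failed to simulate from this x0")
  arr <- simplify2array(sims)  # n_t x 7 x n_ok
  probs <- c((1 - level) / 2, 0.5, 1 - (1 - level) / 2)
  qs <- apply(arr, c(1, 2), quantile, probs = probs, names = FALSE)
  mk <- function(k) {
    m <- qs[k, , ]
    dimnames(m) <- list(NULL, quantities)
    m
  }
  structure(
    list(lower = mk(1), median = mk(2), upper = mk(3), times = t_grid,
         level = level, include_noise = include_noise,
         n_draws = length(sims), n_skipped = n_skipped, method = method),
    class = "uq_bands"
  )
}

#' @export
print.uq_bands <- function(x, ...) {
  cat(sprintf("%s%% %s bands (%s) from %d draws (%d skipped) on %d time points\n",
              format(100 * x$level), if (x$include_noise) "predictive" else "epistemic",
              x$method, x$n_draws, x$n_skipped, length(x$times)))
  invisible(x)
}

#' Export bands as a long data frame (or CSV)
#'
#' @param bands A `uq_bands` object.
#' @param path Optional CSV path.
#' @return Data frame `time, quantity, lower, median, upper`.
#' @export
bands_to_df <- function(bands, path = NULL) {
  qn <- colnames(bands$lower)
  df <- do.call(rbind, lapply(qn, function(q) {
    data.frame(time = bands$times, quantity = q, lower = bands$lower[, q],
               median = bands$median[, q], upper = bands$upper[, q])
  }))
  rownames(df) <- NULL
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  df
}
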