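#' Mean-field variational approximation of the posterior
#'
#' The posterior over the unconstrained parameters is approximated by a fully
#' factorized Gaussian `q(theta) = prod_j N(mu_j, sd_j^2)` fitted by
#' stochastic gradient ascent on the evidence lower bound (ELBO) with the
#' reparameterization `theta = mu + sd * eps`, `eps ~ N(0, I)`. Because the
#' family factorizes, posterior correlations cannot be represented and
#' marginal variances are systematically underestimated wherever the true
#' posterior is correlated.
#'
#' @name vi_uq
NULL

#' Monte-Carlo estimate of the evidence lower bound
#'
#' `ELBO = E_q[log p(D|theta) + log p(theta) - log q(theta)]`, estimated with
#' `n_mc` reparameterized draws. Unbiased for the exact ELBO under the MC
#' scheme; draws hitting a failed simulation (`-Inf` log density) are dropped
#' from the average with a warning.
#'
#' @param vp List with `mu` and `log_sd` vectors (a `variational_params`
#'   object works).
#' @param target A [make_log_density()] bundle or a function
#'   `f(theta, grad = FALSE)` returning the joint log density `log p(D,theta)`.
#' @param n_mc Number of MC samples (>= 1).
#' @param seed Integer seed.
#' @return Scalar ELBO estimate.
#' @export
elbo_estimate <- function(vp, target, n_mc = 100, seed = 1L) {
  stopifnot(n_mc >= 1)
  lp_fn <- if (inherits(target, "log_density_bundle")) target$log_posterior
           else resolve_target(target)
  d <- length(vp$mu)
  sd_q <- exp(vp$log_sd)
  withr::with_seed(seed, {
    vals <- vapply(seq_len(n_mc), function(i) {
      eps <- rnorm(d)
      theta <- vp$mu + sd_q * eps
      as.numeric(lp_fn(theta)) -
        sum(dnorm(theta, vp$mu, sd_q, log = TRUE))
    }, numeric(1))
    bad <- !is.finite(vals)
    if (any(bad)) {
      warning(sum(bad), " of ", n_mc, " ELBO draws hit a failed simulation")
      vals <- vals[!bad]
      if (!length(vals)) return(-Inf)
    }
    mean(vals)
  })
}

#' Fit the mean-field Gaussian by stochastic ELBO ascent
#'
#' Reparameterized gradients of the ELBO with respect to `(mu, log_sd)` are
#' estimated with `n_mc` draws per step (the entropy term is differentiated
#' analytically: its `log_sd`-gradient is identically 1) and followed with
#' Adam. Deterministic given `seed`. If the trace diverges, the best-ELBO
#' iterate seen so far is returned.
#'
#' @param target As in [elbo_estimate()]; must supply gradients
#'   (`grad = TRUE`).
#' @param init_mu Initial mean (e.g. the best ensemble member's parameters).
#' @param init_sd Initial per-coordinate sd (default 0.01).
#' @param n_iters Optimization steps (default 5000).
#' @param n_mc MC samples per step (default 8).
#' @param lr Adam step size.
#' @param seed Integer seed.
#' @return A `variational_params` object: `mu`, `log_sd`, `elbo_trace`.
#' @export
fit_meanfield <- function(target, init_mu, init_sd = 0.01, n_iters = 5000,
                          n_mc = 8, lr = 1e-2, seed = 1L) {
  lp_fn <- if (inherits(target, "log_density_bundle")) target$log_posterior
           else resolve_target(target)
  d <- length(init_mu)
  stopifnot(all(is.finite(init_mu)), init_sd > 0)
  psi <- c(as.numeric(init_mu), rep(log(init_sd), d))
  m <- v <- numeric(2 * d)
  b1 <- 0.9; b2 <- 0.999; eps_a <- 1e-8
  trace <- numeric(n_iters)
  best_elbo <- -Inf; best_psi <- psi
  withr::with_seed(seed, {
    for (it in seq_len(n_iters)) {
      mu <- psi[1:d]; log_sd <- psi[(d + 1):(2 * d)]
      sd_q <- exp(log_sd)
      g_mu <- g_ls <- numeric(d)
      elbo <- 0; n_ok <- 0L
      for (s in seq_len(n_mc)) {
        eps <- rnorm(d)
        theta <- mu + sd_q * eps
        lp <- lp_fn(theta, grad = TRUE)
        if (!is.finite(lp)) next
        g <- attr(lp, "gradient")
        g_mu <- g_mu + g
        g_ls <- g_ls + g * eps * sd_q
        elbo <- elbo + as.numeric(lp) -
          sum(dnorm(theta, mu, sd_q, log = TRUE))
        n_ok <- n_ok + 1L
      }
      if (n_ok == 0L) { trace[it] <- -Inf; next }
      # entropy gradient wrt log_sd is +1 per coordinate
      g_all <- -c(g_mu / n_ok, g_ls / n_ok + 1)  # minimize -ELBO
      m <- b1 * m + (1 - b1) * g_all
      v <- b2 * v + (1 - b2) * g_all^2
      psi <- psi - lr * (m / (1 - b1^it)) / (sqrt(v / (1 - b2^it)) + eps_a)
      trace[it] <- elbo / n_ok
      if (trace[it] > best_elbo) { best_elbo <- trace[it]; best_psi <- psi }
    }
  })
  tail_n <- min(100, n_iters)
  if (n_iters >= 200 &&
      mean(trace[(n_iters - tail_n + 1):n_iters]) < best_elbo - 100) {
    message("ELBO trace deteriorated; returning best-so-far parameters")
    psi <- best_psi
  }
  structure(
    list(mu = psi[1:d], log_sd = psi[(d + 1):(2 * d)], elbo_trace = trace),
    class = "variational_params"
  )
}

#' @export
print.variational_params <- function(x, ...) {
  cat(sprintf("mean-field Gaussian over %d parameters; final ELBO %.3f\n",
              length(x$mu), tail(x$elbo_trace, 1)))
  invisible(x)
}

#' Draw parameter samples from a fitted variational approximation
#'
#' @param vp A `variational_params` object.
#' @param n Number of iid draws.
#' @param seed Integer seed.
#' @return Matrix n x n_params of unconstrained draws.
#' @export
sample_variational <- function(vp, n, seed = 1L) {
  stopifnot(n >= 1)
  d <- length(vp$mu)
  withr::with_seed(seed, {
    eps <- matrix(rnorm(n * d), n, d)
    sweep(eps, 2, exp(vp$log_sd), `*`) + rep(vp$mu, each = n)
  })
}

#' Bands from a variational approximation
#'
#' Draws `n_draws` parameter samples from `q` and reuses the shared band
#' machinery, so band semantics are identical across back-ends.
#'
#' @inheritParams posterior_bands
#' @param vp A `variational_params` object.
#' @param n_draws Number of samples from `q`.
#' @export
variational_bands <- function(vp, model, t_grid, x0 = model$x0, level = 0.99,
                              include_noise = FALSE, n_draws = 500,
                              seed = 1L) {
  s <- sample_variational(vp, n_draws, seed = seed)
  draws <- lapply(seq_len(nrow(s)), function(i)
    setNames(s[i, ], model$par_names))
  trajectory_bands(draws, model, t_grid, x0 = x0, level = level,
                   include_noise = include_noise, seed = seed + 1L,
                   method = "vi")
}
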