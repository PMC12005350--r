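# resolve a sampling target: either a log_density_bundle (use its posterior)
# or a plain function(theta, grad = FALSE) returning the log density with an
# optional "gradient" attribute
resolve_target <- function(target) {
  if (inherits(target, "log_density_bundle")) target$log_posterior
  else if (is.function(target)) target
  else stop("target must be a log_density_bundle or a function")
}

# one leapfrog step; minv is the per-coordinate inverse mass (metric diagonal)
leapfrog <- function(theta, r, grad, eps, minv, lp_fn) {
  r <- r + 0.5 * eps * grad
  theta <- theta + eps * minv * r
  lp <- lp_fn(theta, grad = TRUE)
  g <- attr(lp, "gradient")
  r <- r + 0.5 * eps * g
  list(theta = theta, r = r, lp = as.numeric(lp), grad = g)
}

joint_lp <- function(lp, r, minv) lp - 0.5 * sum(r^2 * minv)

find_reasonable_eps <- function(theta, lp_fn, minv) {
  d <- length(theta)
  eps <- 1
  r <- rnorm(d, 0, 1 / sqrt(minv))
  lp0 <- lp_fn(theta, grad = TRUE)
  h0 <- joint_lp(as.numeric(lp0), r, minv)
  st <- leapfrog(theta, r, attr(lp0, "gradient"), eps, minv, lp_fn)
  h1 <- joint_lp(st$lp, st$r, minv)
  if (!is.finite(h1)) { eps <- eps / 2
    st <- leapfrog(theta, r, attr(lp0, "gradient"), eps, minv, lp_fn)
    h1 <- joint_lp(st$lp, st$r, minv)
  }
  a <- if (is.finite(h1) && h1 - h0 > log(0.5)) 1 else -1
  for (i in 1:50) {
    eps <- eps * 2^a
    st <- leapfrog(theta, r, attr(lp0, "gradient"), eps, minv, lp_fn)
    h1 <- joint_lp(st$lp, st$r, minv)
    ok <- is.finite(h1) && a * (h1 - h0) > -a * log(2)
    if (!ok) break
  }
  eps
}

# No-U-Turn sampler with slice variable (recursive doubling), dual-averaging
# step-size adaptation toward a target acceptance statistic, and a diagonal
# metric estimated from the second half of warmup.
nuts_chain <- function(lp_fn, init, n_samples, n_warmup, target_accept,
                       max_treedepth, seed) {
  set.seed(seed)
  d <- length(init)
  minv <- rep(1, d)
  theta <- init
  delta_max <- 1000

  build_tree <- function(theta, r, grad, logu, v, j, eps, h0) {
    if (j == 0) {
      st <- leapfrog(theta, r, grad, v * eps, minv, lp_fn)
      h <- joint_lp(st$lp, st$r, minv)
      n1 <- if (is.finite(h) && logu <= h) 1L else 0L
      s1 <- is.finite(h) && (logu < h + delta_max)
      list(tm = st$theta, rm = st$r, gm = st$grad, tp = st$theta, rp = st$r,
           gp = st$grad, tprime = st$theta, lprime = st$lp, n = n1, s = s1,
           alpha = min(1, exp(h - h0)), nalpha = 1L,
           div = !s1)
    } else {
      t1 <- build_tree(theta, r, grad, logu, v, j - 1, eps, h0)
      if (t1$s) {
        if (v == -1) {
          t2 <- build_tree(t1$tm, t1$rm, t1$gm, logu, v, j - 1, eps, h0)
          t1$tm <- t2$tm; t1$rm <- t2$rm; t1$gm <- t2$gm
        } else {
          t2 <- build_tree(t1$tp, t1$rp, t1$gp, logu, v, j - 1, eps, h0)
          t1$tp <- t2$tp; t1$rp <- t2$rp; t1$gp <- t2$gp
        }
        if (t2$n > 0 && runif(1) < t2$n / max(t1$n + t2$n, 1L)) {
          t1$tprime <- t2$tprime; t1$lprime <- t2$lprime
        }
        dtheta <- t1$tp - t1$tm
        t1$s <- t2$s && sum(dtheta * (minv * t1$rm)) >= 0 &&
          sum(dtheta * (minv * t1$rp)) >= 0
        t1$n <- t1$n + t2$n
        t1$alpha <- t1$alpha + t2$alpha
        t1$nalpha <- t1$nalpha + t2$nalpha
        t1$div <- t1$div || t2$div
      }
      t1
    }
  }

  run_phase <- function(theta, n_iter, adapt, eps0, store) {
    # dual averaging state
    eps <- eps0; mu <- log(10 * eps0)
    hbar <- 0; log_eps_bar <- log(eps0)
    gamma <- 0.05; t0 <- 10; kappa <- 0.75
    draws <- if (store) matrix(NA_real_, n_iter, d) else NULL
    lps <- numeric(n_iter)
    divergences <- 0L
    lp_cur <- lp_fn(theta, grad = TRUE)
    for (it in seq_len(n_iter)) {
      r0 <- rnorm(d, 0, 1 / sqrt(minv))
      h0 <- joint_lp(as.numeric(lp_cur), r0, minv)
      logu <- h0 - rexp(1)
      tm <- tp <- theta; rm <- rp <- r0
      gm <- gp <- attr(lp_cur, "gradient")
      tprime <- theta; lprime <- as.numeric(lp_cur)
      j <- 0L; n <- 1L; s <- TRUE
      alpha <- 0; nalpha <- 1L
      while (s && j < max_treedepth) {
        v <- sample(c(-1, 1), 1)
        if (v == -1) {
          tr <- build_tree(tm, rm, gm, logu, v, j, eps, h0)
          tm <- tr$tm; rm <- tr$rm; gm <- tr$gm
        } else {
          tr <- build_tree(tp, rp, gp, logu, v, j, eps, h0)
          tp <- tr$tp; rp <- tr$rp; gp <- tr$gp
        }
        if (tr$s && tr$n > 0 && runif(1) < min(1, tr$n / n)) {
          tprime <- tr$tprime; lprime <- tr$lprime
        }
        n <- n + tr$n
        dtheta <- tp - tm
        s <- tr$s && sum(dtheta * (minv * rm)) >= 0 &&
          sum(dtheta * (minv * rp)) >= 0
        alpha <- tr$alpha; nalpha <- tr$nalpha
        if (tr$div) divergences <- divergences + 1L
        j <- j + 1L
      }
      if (!identical(tprime, theta)) {
        theta <- tprime
        lp_cur <- lp_fn(theta, grad = TRUE)
      }
      if (adapt) {
        w <- 1 / (it + t0)
        hbar <- (1 - w) * hbar + w * (target_accept - alpha / nalpha)
        log_eps <- mu - sqrt(it) / gamma * hbar
        eta <- it^(-kappa)
        log_eps_bar <- eta * log_eps + (1 - eta) * log_eps_bar
        eps <- exp(log_eps)
      }
      if (store) draws[it, ] <- theta
      lps[it] <- as.numeric(lp_cur)
    }
    list(theta = theta, eps = exp(log_eps_bar), draws = draws, lps = lps,
         divergences = divergences)
  }

  eps0 <- find_reasonable_eps(theta, lp_fn, minv)
  n1 <- max(20L, floor(n_warmup / 2))
  ph1 <- run_phase(theta, n1, adapt = TRUE, eps0 = eps0, store = TRUE)
  v_est <- apply(ph1$draws[max(1, floor(n1 / 2)):n1, , drop = FALSE], 2, var)
  v_est[!is.finite(v_est) | v_est < 1e-10] <- 1
  minv <- v_est  # build_tree closes over this environment, so it sees the update
  ph2 <- run_phase(ph1$theta, max(0L, n_warmup - n1), adapt = TRUE,
                   eps0 = find_reasonable_eps(ph1$theta, lp_fn, minv),
                   store = FALSE)
  ph3 <- run_phase(ph2$theta, n_samples, adapt = FALSE, eps0 = ph2$eps,
                   store = TRUE)
  list(draws = ph3$draws, lps = ph3$lps,
       divergences = ph1$divergences + ph2$divergences + ph3$divergences,
       eps = ph2$eps)
}

#' Sample the posterior with the No-U-Turn Sampler
#'
#' Gradient-based Hamiltonian Monte Carlo with recursive trajectory doubling
#' and automatic termination (the no-U-turn criterion). Warmup adapts the
#' step size by dual averaging toward `target_accept` and estimates a
#' diagonal metric from warmup draws. One chain is run per initialization;
#' runs are deterministic given `seed`.
#'
#' @param target A [make_log_density()] bundle (its `log_posterior` is
#'   sampled) or any function `f(theta, grad = FALSE)` returning a log
#'   density with attribute `"gradient"` when `grad = TRUE`.
#' @param inits List of initial parameter vectors (one chain each).
#' @param n_samples Post-warmup draws per chain.
#' @param n_warmup Warmup iterations (default `n_samples`).
#' @param seed Integer seed.
#' @param target_accept Dual-averaging target acceptance statistic.
#' @param max_treedepth Maximum trajectory doublings per iteration.
#' @return A `chain_set`: `draws` (n_chains x n_samples x n_params),
#'   `log_posts`, `diagnostics` (split R-hat and effective sample size per
#'   parameter), `divergences`, `algo = "nuts"`.
#' @export
run_nuts <- function(target, inits, n_samples = 1000, n_warmup = n_samples,
                     seed = 1L, target_accept = 0.8, max_treedepth = 10) {
  lp_fn <- resolve_target(target)
  if (!is.list(inits)) inits <- list(inits)
  d <- length(inits[[1]])
  chains <- lapply(seq_along(inits), function(c) {
    nuts_chain(lp_fn, as.numeric(inits[[c]]), n_samples, n_warmup,
               target_accept, max_treedepth, seed = seed + c - 1L)
  })
  draws <- array(NA_real_, c(length(chains), n_samples, d))
  lps <- matrix(NA_real_, length(chains), n_samples)
  for (c in seq_along(chains)) {
    draws[c, , ] <- chains[[c]]$draws
    lps[c, ] <- chains[[c]]$lps
  }
  new_chain_set(draws, lps, algo = "nuts",
                divergences = sum(vapply(chains, `[[`, integer(1),
                                         "divergences")))
}

new_chain_set <- function(draws, log_posts, algo, temperatures = 1,
                          swap_acceptance = NULL, divergences = 0L) {
  d <- dim(draws)[3]
  diag_df <- data.frame(
    param = paste0("p", seq_len(d)),
    rhat = vapply(seq_len(d), function(j) split_rhat(draws[, , j, drop = FALSE]),
                  numeric(1)),
    ess = vapply(seq_len(d), function(j) ess_basic(draws[, , j, drop = FALSE]),
                 numeric(1))
  )
  structure(
    list(draws = draws, log_posts = log_posts, temperatures = temperatures,
         swap_acceptance = swap_acceptance, diagnostics = diag_df,
         divergences = divergences, algo = algo),
    class = "chain_set"
  )
}

#' @export
print.chain_set <- function(x, ...) {
  dm <- dim(x$draws)
  cat(sprintf("%s chain set: %d chain(s) x %d draws x %d parameters\n",
              toupper(x$algo), dm[1], dm[2], dm[3]))
  cat(sprintf("  max split R-hat: %.3f, min ESS: %.0f\n",
              max(x$diagnostics$rhat, na.rm = TRUE),
              min(x$diagnostics$ess, na.rm = TRUE)))
  if (!is.null(x$swap_acceptance))
    cat("  swap acceptance:", paste(sprintf("%.2f", x$swap_acceptance),
                                    collapse = " "), "\n")
  invisible(x)
}

#' Sample a multimodal posterior with parallel tempering
#'
#' Runs one chain per temperature on the flattened densities
#' `log p(theta) / T`; within-chain updates are adaptive random-walk
#' Metropolis (per-coordinate proposal scales and a global step factor
#' adapted during burn-in, then frozen). Every `swap_every` iterations,
#' adjacent temperature pairs propose a state swap accepted with probability
#' `min(1, exp((1/T_i - 1/T_j) * (lp_j - lp_i)))`. Only the cold (T = 1)
#' chain's post-burn-in draws enter the returned sample.
#'
#' @param target As in [run_nuts()] (gradients are not required).
#' @param init Initial parameter vector (all temperatures start here), or a
#'   list with one vector per temperature.
#' @param ladder Strictly increasing temperature ladder starting at 1
#'   (default 6 rungs, geometric from 1 to 50). A length-1 ladder degenerates
#'   to plain adaptive Metropolis.
#' @param n_samples Post-burn-in cold-chain draws.
#' @param n_burn Burn-in iterations (default `n_samples`).
#' @param swap_every Iterations between swap sweeps.
#' @param seed Integer seed.
#' @return A `chain_set` with cold-chain `draws` (1 x n_samples x n_params),
#'   `temperatures`, and per-adjacent-pair `swap_acceptance`.
#' @export
run_parallel_tempering <- function(target, init,
                                   ladder = exp(seq(log(1), log(50),
                                                    length.out = 6)),
                                   n_samples = 2000, n_burn = n_samples,
                                   swap_every = 10, seed = 1L) {
  lp_fn <- resolve_target(target)
  if (abs(ladder[1] - 1) > 1e-12) stop("ladder must start at temperature 1")
  if (length(ladder) > 1 && any(diff(ladder) <= 0))
    stop("ladder must be strictly increasing")
  set.seed(seed)
  K <- length(ladder)
  states <- if (is.list(init)) lapply(init, as.numeric)
            else rep(list(as.numeric(init)), K)
  d <- length(states[[1]])
  lps <- vapply(states, function(s) as.numeric(lp_fn(s)), numeric(1))
  if (!is.finite(lps[1])) stop("initial state has non-finite log density")

  scale <- rep(2.38 / sqrt(d), K)
  # Roberts-Rosenthal optimal acceptance: 0.44 in one dimension, 0.234 beyond
  acc_target <- if (d == 1) 0.44 else 0.234
  prop_sd <- matrix(1, K, d)
  # Welford accumulators for per-coordinate proposal sds (burn-in only)
  wf_n <- 0; wf_mean <- matrix(0, K, d); wf_m2 <- matrix(0, K, d)
  acc_ct <- rej_ct <- rep(0L, K)
  n_batch <- 0
  swap_acc <- swap_try <- rep(0L, max(K - 1, 1))

  n_total <- n_burn + n_samples
  draws <- matrix(NA_real_, n_samples, d)
  cold_lps <- numeric(n_samples)

  for (it in seq_len(n_total)) {
    adapting <- it <= n_burn
    for (k in seq_len(K)) {
      prop <- states[[k]] + rnorm(d) * scale[k] * prop_sd[k, ]
      lp_new <- as.numeric(lp_fn(prop))
      if (is.finite(lp_new) &&
          log(runif(1)) < (lp_new - lps[k]) / ladder[k]) {
        states[[k]] <- prop; lps[k] <- lp_new
        acc_ct[k] <- acc_ct[k] + 1L
      } else rej_ct[k] <- rej_ct[k] + 1L
    }
    if (adapting) {
      wf_n <- wf_n + 1
      for (k in seq_len(K)) {
        delta <- states[[k]] - wf_mean[k, ]
        wf_mean[k, ] <- wf_mean[k, ] + delta / wf_n
        wf_m2[k, ] <- wf_m2[k, ] + delta * (states[[k]] - wf_mean[k, ])
      }
      if (it %% 50 == 0) {
        # diminishing adaptation toward the optimal acceptance rate
        n_batch <- n_batch + 1
        rate <- acc_ct / pmax(acc_ct + rej_ct, 1)
        scale <- scale * exp((rate - acc_target) / sqrt(n_batch))
        acc_ct <- rej_ct <- rep(0L, K)
        if (wf_n > 10) {
          sds <- sqrt(wf_m2 / (wf_n - 1))
          sds[!is.finite(sds) | sds < 1e-8] <- 1e-8
          prop_sd <- sds
        }
      }
    }
    if (K > 1 && it %% swap_every == 0) {
      for (k in seq_len(K - 1)) {
        swap_try[k] <- swap_try[k] + 1L
        log_a <- (1 / ladder[k] - 1 / ladder[k + 1]) * (lps[k + 1] - lps[k])
        if (log(runif(1)) < log_a) {
          tmp <- states[[k]]; states[[k]] <- states[[k + 1]]
          states[[k + 1]] <- tmp
          tmp <- lps[k]; lps[k] <- lps[k + 1]; lps[k + 1] <- tmp
          swap_acc[k] <- swap_acc[k] + 1L
        }
      }
    }
    if (it > n_burn) {
      draws[it - n_burn, ] <- states[[1]]
      cold_lps[it - n_burn] <- lps[1]
    }
  }
  arr <- array(NA_real_, c(1, n_samples, d))
  arr[1, , ] <- draws
  new_chain_set(arr, matrix(cold_lps, 1), algo = "pt",
                temperatures = ladder,
                swap_acceptance = if (K > 1) swap_acc / pmax(swap_try, 1)
                                  else NULL)
}

#' Initialize sampling chains at optimization endpoints
#'
#' Takes the `n_chains` accepted ensemble members with lowest combined-data
#' NLL as starting points; if fewer members exist, they are recycled with
#' small Gaussian jitter (logged via a message).
#'
#' @param ensemble_result An `ensemble_result`.
#' @param n_chains Number of initializations needed.
#' @param jitter_sd Jitter scale used when recycling.
#' @param seed Seed for the jitter.
#' @return List of unconstrained parameter vectors.
#' @export
init_from_optimization <- function(ensemble_result, n_chains = 4,
                                   jitter_sd = 0.01, seed = 1L) {
  stopifnot(inherits(ensemble_result, "ensemble_result"),
            length(ensemble_result$members) >= 1)
  ord <- order(vapply(ensemble_result$members, `[[`, numeric(1), "full_nll"))
  pars <- lapply(ensemble_result$members[ord], `[[`, "final_params")
  if (length(pars) >= n_chains) return(pars[seq_len(n_chains)])
  message("recycling ", length(pars), " members into ", n_chains,
          " chain initializations with jitter")
  withr::with_seed(seed, {
    lapply(seq_len(n_chains), function(i) {
      base <- pars[[(i - 1) %% length(pars) + 1]]
      if (i <= length(pars)) base
      else base + rnorm(length(base), sd = jitter_sd)
    })
  })
}

#' Posterior(-predictive) bands from sampler draws
#'
#' Same band semantics as [ensemble_bands()], computed over (thinned)
#' cold-chain draws: epistemic bands use the mean trajectories, and
#' `include_noise = TRUE` convolves the observables with per-draw observation
#' noise (the posterior predictive).
#'
#' @param chains A `chain_set`.
#' @param model The fitted [ude_model()].
#' @param t_grid Output times.
#' @param x0 Initial state.
#' @param level Band level.
#' @param include_noise Posterior-predictive bands?
#' @param thin Keep at most this many draws (evenly spaced; default 1000).
#' @param seed Seed for noise draws.
#' @param method Label stored on the result.
#' @return A `uq_bands` object.
#' @export
posterior_bands <- function(chains, model, t_grid, x0 = model$x0,
                            level = 0.99, include_noise = FALSE, thin = 1000,
                            seed = 1L, method = "mcmc") {
  stopifnot(inherits(chains, "chain_set"))
  dm <- dim(chains$draws)
  flat <- matrix(aperm(chains$draws, c(2, 1, 3)), dm[1] * dm[2], dm[3])
  keep <- unique(round(seq(1, nrow(flat), length.out = min(thin, nrow(flat)))))
  draws <- lapply(keep, function(i) setNames(flat[i, ], model$par_names))
  trajectory_bands(draws, model, t_grid, x0 = x0, level = level,
                   include_noise = include_noise, seed = seed, method = method)
}
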