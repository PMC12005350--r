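#' Draw ensemble initializations from the prior
#'
#' Multi-start training begins at iid draws from the model prior on the
#' unconstrained parameter space; the prior's only other role in the ensemble
#' back-end is this initialization (bounds still constrain updates through
#' the tanh transform).
#'
#' @param model A [ude_model()].
#' @param m Number of draws (>= 1).
#' @param seed Integer seed; draws are deterministic given it.
#' @return List of `m` unconstrained parameter vectors.
#' @export
sample_initializations <- function(model, m, seed = 1L) {
  if (m < 1) stop("m must be >= 1")
  p <- model$prior
  mean_vec <- c(0, 0, rep(0, model$network$n_params), p$mean_noise)
  sd_vec <- c(p$sd_mech, p$sd_mech, rep(p$sd_net, model$network$n_params),
              p$sd_noise)
  withr::with_seed(seed, {
    lapply(seq_len(m), function(i)
      setNames(rnorm(model$n_params, mean_vec, sd_vec), model$par_names))
  })
}

#' Assign a random train/validation split to a dataset
#'
#' Point-level partition without replacement: `floor(n * (1 - val_fraction))`
#' training points, the rest validation. Each ensemble member receives its
#' own split seed, which is the second source of randomness (besides the
#' initialization) in the ensemble.
#'
#' @param data A `ude_dataset`.
#' @param val_fraction Fraction of points held out, in (0, 1).
#' @param seed Integer seed.
#' @return The dataset with its `split_mask` set to `"train"`/`"val"`.
#' @export
split_data <- function(data, val_fraction = 0.2, seed = 1L) {
  n <- length(data$times)
  if (val_fraction <= 0 || val_fraction >= 1)
    stop("val_fraction must be in (0, 1)")
  n_train <- floor(n * (1 - val_fraction))
  if (n_train < 1 || n_train >= n)
    stop("split would leave an empty train or validation set")
  idx <- withr::with_seed(seed, sample.int(n, n_train))
  mask <- rep("val", n)
  mask[idx] <- "train"
  data$split_mask <- mask
  data
}

#' Train one ensemble member with early stopping and L2 regularization
#'
#' Minimizes the training negative log-likelihood plus an L2 penalty on the
#' network weights by a first-order adaptive optimizer (Adam), monitoring the
#' unpenalized validation NLL each epoch. The returned parameters are those
#' of the best validation epoch; the NLL on the combined dataset — used only
#' for subselection — is recorded at those parameters.
#'
#' @param init Unconstrained initial parameter vector.
#' @param data A `ude_dataset` whose `split_mask` marks train/validation.
#' @param model A [ude_model()].
#' @param control List: `n_epochs` (default 2000), `lr` (1e-2), `lambda_l2`
#'   (1e-4, network weights only), `patience` (100 epochs on validation NLL).
#' @return An `ensemble_member`: `init_params`, `final_params`, `train_nll`,
#'   `val_nll`, `full_nll`, `n_epochs_run`, `best_epoch`, `converged`,
#'   `val_curve`.
#' @export
train_member <- function(init, data, model, control = list()) {
  ctl <- utils::modifyList(
    list(n_epochs = 2000, lr = 1e-2, lambda_l2 = 1e-4, patience = 100),
    control)
  train_idx <- which(data$split_mask == "train")
  val_idx <- which(data$split_mask == "val")
  if (!length(train_idx) || !length(val_idx))
    stop("train_member needs a dataset with a train/validation split")
  jn <- idx_net(model)
  noise_j <- idx_noise(model)

  theta <- init
  m <- v <- numeric(model$n_params)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best_val <- Inf; best_theta <- init; best_epoch <- 0L
  best_train <- Inf
  val_curve <- numeric(0)
  epoch <- 0L

  for (epoch in seq_len(ctl$n_epochs)) {
    fw <- solve_forward(theta, model, data$times, sens = TRUE)
    if (!fw$ok) { val_curve <- c(val_curve, Inf); break }
    noise <- transform_noise(theta[[noise_j]])
    od <- obs_logdens(data$y, fw$yhat, noise, model$noise_model, grad = TRUE)
    ll_train <- sum(od$ll[train_idx, ])
    ll_val <- sum(od$ll[val_idx, ])
    val_curve <- c(val_curve, -ll_val)
    if (-ll_val < best_val) {
      best_val <- -ll_val; best_theta <- theta
      best_epoch <- epoch; best_train <- -ll_train
    } else if (epoch - best_epoch >= ctl$patience) break

    dmu <- od$dmu; dmu[val_idx, ] <- 0
    g_ll <- apply(fw$sens_y * as.vector(dmu), 3, sum)
    g_ll[noise_j] <- sum(od$dlognoise[train_idx, ])
    g <- -g_ll  # minimize NLL
    g[jn] <- g[jn] + 2 * ctl$lambda_l2 * theta[jn]
    if (!all(is.finite(g))) break

    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    theta <- theta - ctl$lr * (m / (1 - b1^epoch)) /
      (sqrt(v / (1 - b2^epoch)) + eps)
  }

  full_nll <- -as.numeric(log_likelihood(best_theta, data, model))
  structure(
    list(init_params = init, final_params = best_theta,
         train_nll = best_train, val_nll = best_val, full_nll = full_nll,
         n_epochs_run = epoch, best_epoch = best_epoch,
         converged = is.finite(full_nll), val_curve = val_curve),
    class = "ensemble_member"
  )
}

#' Likelihood-ratio cutoff for ensemble subselection
#'
#' The acceptance threshold for the statistic
#' `lambda = 2 * (NLL(member) - NLL(best))` is the `alpha`-quantile of a
#' chi-squared distribution with `nf` degrees of freedom; `nf = 1` gives a
#' lower bound on the uncertainty.
#'
#' @param alpha Significance level in (0, 1).
#' @param nf Degrees of freedom (>= 1).
#' @return The quantile (scalar).
#' @export
chi2_threshold <- function(alpha = 0.95, nf = 1) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (nf < 1) stop("nf must be >= 1")
  qchisq(alpha, df = nf)
}

#' Subselect ensemble members by the likelihood-ratio criterion
#'
#' The member with minimal combined-data NLL proxies the maximum-likelihood
#' estimate; any member whose likelihood-ratio statistic against it stays
#' below the chi-squared cutoff is accepted (the best member always accepts
#' itself, lambda = 0).
#'
#' @param members List of `ensemble_member`s.
#' @param alpha,nf Passed to [chi2_threshold()].
#' @return An `ensemble_result`: accepted `members`, `best`, `threshold`,
#'   `alpha`, `nf`, and an `acceptance` data frame (one row per converged
#'   member: `full_nll`, `lambda`, `accepted`) whose NLL-sorted order is the
#'   waterfall plot.
#' @export
subselect <- function(members, alpha = 0.95, nf = 1) {
  conv <- Filter(function(m) isTRUE(m$converged), members)
  if (!length(conv)) stop("no converged ensemble members to subselect from")
  nll <- vapply(conv, function(m) m$full_nll, numeric(1))
  best_i <- which.min(nll)
  lambda <- 2 * (nll - nll[best_i])
  thr <- chi2_threshold(alpha, nf)
  acc <- lambda <= thr
  structure(
    list(members = conv[acc], best = conv[[best_i]], threshold = thr,
         alpha = alpha, nf = nf,
         acceptance = data.frame(member = seq_along(conv), full_nll = nll,
                                 lambda = lambda, accepted = acc)),
    class = "ensemble_result"
  )
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf(
    "UDE ensemble: %d/%d converged members accepted (alpha=%.2f, nf=%d, cutoff=%.3f)\n",
    length(x$members), nrow(x$acceptance), x$alpha, x$nf, x$threshold))
  cat(sprintf("  best full-data NLL: %.4f\n", x$best$full_nll))
  invisible(x)
}

#' Fit a multi-start ensemble end to end
#'
#' Samples `m` initializations from the prior, gives each member its own
#' random train/validation split, trains each with early stopping and L2
#' regularization, and subselects by the likelihood-ratio criterion.
#'
#' @param data A `ude_dataset`.
#' @param model A [ude_model()].
#' @param m Number of candidate members.
#' @param alpha,nf Subselection settings (see [chi2_threshold()]).
#' @param val_fraction Held-out fraction per member.
#' @param seed Master seed; member-level seeds derive from it.
#' @param control Training control passed to [train_member()].
#' @return An `ensemble_result` (also carries `all_members`).
#' @export
fit_ensemble <- function(data, model, m = 100, alpha = 0.95, nf = 1,
                         val_fraction = 0.2, seed = 1L, control = list()) {
  inits <- sample_initializations(model, m, seed = seed)
  split_seeds <- withr::with_seed(seed + 1L, sample.int(.Machine$integer.max, m))
  members <- lapply(seq_len(m), function(i) {
    di <- split_data(data, val_fraction, seed = split_seeds[i])
    train_member(inits[[i]], di, model, control)
  })
  res <- subselect(members, alpha = alpha, nf = nf)
  res$all_members <- members
  res
}

#' Acceptance count as a function of the significance level
#'
#' Subselecting a different fraction of the best models is equivalent to
#' moving the significance level of the chi-squared test; this utility sweeps
#' alpha and reports how many members each cutoff admits.
#'
#' @param members List of `ensemble_member`s (e.g. `result$all_members`).
#' @param alphas Levels to sweep.
#' @param nf Degrees of freedom.
#' @return Data frame with `alpha`, `threshold`, `n_accepted`.
#' @export
alpha_sensitivity <- function(members, alphas = c(0.5, 0.8, 0.9, 0.95, 0.99),
                              nf = 1) {
  do.call(rbind, lapply(alphas, function(a) {
    r <- subselect(members, alpha = a, nf = nf)
    data.frame(alpha = a, threshold = r$threshold,
               n_accepted = length(r$members))
  }))
}

#' Prediction/uncertainty bands from an accepted ensemble
#'
#' Simulates every accepted member from `x0` on `t_grid` and takes pointwise
#' equal-tailed percentile bands over members for each state (including the
#' unobserved S and E), the network transmission rate beta(t), and the
#' observables. With `include_noise = TRUE` the observable bands become
#' predictive: each member's trajectory is convolved with a draw from its own
#' noise model before the percentiles are taken (epistemic + aleatoric).
#'
#' @param result An `ensemble_result`.
#' @param model The [ude_model()] used for fitting.
#' @param t_grid Output times.
#' @param x0 Initial state (defaults to the model's; pass a new one for
#'   generalization experiments).
#' @param level Band level, e.g. 0.99.
#' @param include_noise Add observation noise to the observable bands?
#' @param seed Seed for the noise draws.
#' @return A `uq_bands` object (see [trajectory_bands()]).
#' @export
ensemble_bands <- function(result, model, t_grid, x0 = model$x0, level = 0.99,
                           include_noise = FALSE, seed = 1L) {
  stopifnot(inherits(result, "ensemble_result"))
  draws <- lapply(result$members, function(m) m$final_params)
  trajectory_bands(draws, model, t_grid, x0 = x0, level = level,
                   include_noise = include_noise, seed = seed,
                   method = "ensemble")
}
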