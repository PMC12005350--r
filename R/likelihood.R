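#' Forward-simulate the UDE and (optionally) its sensitivities
#'
#' Integrates the SEIR skeleton with the network-supplied beta(t) by classical
#' fixed-step RK4 in compiled code and returns the states, the network rate on
#' the grid, and the predicted observables `yhat = (I, R)`. With
#' `sens = TRUE`, forward sensitivities are propagated through the identical
#' discretization, yielding the exact gradient of the numerical solution with
#' respect to all ODE-relevant parameters (unconstrained scale, chain rule
#' through the tanh bounds applied here).
#'
#' @param theta_u Unconstrained parameter vector (`model$par_names` layout).
#' @param model A [ude_model()].
#' @param t_grid Output times (days), non-decreasing, starting at or after 0.
#' @param x0 Initial state; defaults to the model's.
#' @param sens Propagate sensitivities?
#' @return List: `states` (n_t x 4), `beta`, `yhat` (n_t x 2), `ok` (FALSE
#'   flags a failed simulation — non-finite or exploding states), and if
#'   requested `sens_y`, an n_t x 2 x n_params array d yhat / d theta_u
#'   (the noise coordinate is identically zero).
#' @export
solve_forward <- function(theta_u, model, t_grid, x0 = model$x0, sens = FALSE) {
  cp <- constrain_params(theta_u, model)
  net <- model$network
  sol <- ude_solve_cpp(as.numeric(x0), as.numeric(t_grid), 0,
                       cp$alpha, cp$gamma, model$N,
                       cp$theta_net, net$sizes, net$t_max, net$beta_max,
                       model$dt, sens)
  colnames(sol$states) <- c("S", "E", "I", "R")
  out <- list(states = sol$states, beta = sol$beta,
              yhat = sol$states[, c("I", "R"), drop = FALSE], ok = sol$ok)
  if (sens && sol$ok) {
    n_t <- length(t_grid)
    b <- model$bounds
    # chain rule: compiled sensitivities are wrt constrained (alpha, gamma, net)
    jac <- c(dtransform_mech(theta_u[[1]], b$alpha[1], b$alpha[2]),
             dtransform_mech(theta_u[[2]], b$gamma[1], b$gamma[2]),
             rep(1, net$n_params))
    sens_u <- sol$sens * rep(jac, each = n_t * 4L)
    sens_y <- array(0, dim = c(n_t, 2L, model$n_params))
    sens_y[, , -model$n_params] <- sens_u[, 3:4, , drop = FALSE]
    out$sens_y <- sens_y
  }
  out
}

# pointwise log-density of the observations given predictions, with the
# derivative wrt the prediction and wrt the log noise parameter
obs_logdens <- function(y, yhat, noise, noise_model, grad = FALSE) {
  if (noise_model == "gaussian") {
    ll <- dnorm(y, mean = yhat, sd = noise, log = TRUE)
    if (!grad) return(list(ll = ll))
    r <- y - yhat
    list(ll = ll, dmu = r / noise^2, dlognoise = r^2 / noise^2 - 1)
  } else {
    mu <- pmax(yhat, 1e-10)
    ll <- dnbinom(y, size = noise, mu = mu, log = TRUE)
    if (!grad) return(list(ll = ll))
    dmu <- ifelse(yhat > 1e-10, y / mu - (y + noise) / (noise + mu), 0)
    dlogd <- noise * (digamma(y + noise) - digamma(noise) +
                        log(noise / (noise + mu)) + 1 - (y + noise) / (noise + mu))
    list(ll = ll, dmu = dmu, dlognoise = dlogd)
  }
}

#' Log-likelihood of a dataset under the UDE model
#'
#' Sums the log observation density over time points and observables:
#' Gaussian `N(y; yhat, sigma^2)` or negative binomial with mean `yhat` and
#' dispersion `d` (Var = mu + mu^2/d). A failed forward simulation yields
#' `-Inf` (a sentinel the samplers reject and the ensemble discards — never
#' an error).
#'
#' @param theta_u Unconstrained parameter vector.
#' @param data A `ude_dataset`.
#' @param model A [ude_model()]; its `noise_model` must match the data's.
#' @param subset Optional logical/integer index over time points (train or
#'   validation rows); default all.
#' @param grad If `TRUE`, attach the exact gradient as attribute `"gradient"`.
#' @return Scalar log-likelihood (with optional gradient attribute).
#' @export
log_likelihood <- function(theta_u, data, model, subset = NULL, grad = FALSE) {
  if (data$noise_model != model$noise_model)
    stop("data noise model (", data$noise_model,
         ") does not match the model's (", model$noise_model, ")")
  fw <- solve_forward(theta_u, model, data$times, sens = grad)
  if (!fw$ok) {
    out <- -Inf
    if (grad) attr(out, "gradient") <- rep(0, model$n_params)
    return(out)
  }
  rows <- if (is.null(subset)) seq_along(data$times) else subset
  noise <- transform_noise(theta_u[[idx_noise(model)]])
  y <- data$y[rows, , drop = FALSE]
  yhat <- fw$yhat[rows, , drop = FALSE]
  od <- obs_logdens(y, yhat, noise, model$noise_model, grad = grad)
  out <- sum(od$ll)
  if (grad) {
    g <- rep(0, model$n_params)
    sy <- fw$sens_y[rows, , , drop = FALSE]
    # contract dll/dyhat with d yhat/d theta over points x observables
    g <- apply(sy * as.vector(od$dmu), 3, sum)
    g[model$n_params] <- sum(od$dlognoise)
    attr(out, "gradient") <- g
  }
  out
}

#' Log-prior over the unconstrained parameters
#'
#' Independent Gaussians: isotropic `N(0, sd_net^2)` on the network weights,
#' `N(0, sd_mech^2)` on the unconstrained mechanistic rates (a bell over the
#' bounded interval after the tanh pushforward), and
#' `N(mean_noise, sd_noise^2)` on the log noise parameter. Finite everywhere.
#'
#' @inheritParams log_likelihood
#' @return Scalar log-prior (with optional gradient attribute).
#' @export
log_prior <- function(theta_u, model, grad = FALSE) {
  p <- model$prior
  mean_vec <- c(0, 0, rep(0, model$network$n_params), p$mean_noise)
  sd_vec <- c(p$sd_mech, p$sd_mech, rep(p$sd_net, model$network$n_params),
              p$sd_noise)
  out <- sum(dnorm(theta_u, mean_vec, sd_vec, log = TRUE))
  if (grad) attr(out, "gradient") <- -(as.numeric(theta_u) - mean_vec) / sd_vec^2
  out
}

#' Bundle the log-likelihood, log-prior and log-posterior of a fit problem
#'
#' The bundle is the single objective surface shared by the three
#' uncertainty-quantification back-ends. `log_posterior` is the sum of
#' likelihood and prior (the evidence constant of Bayes' rule is dropped, so
#' only differences are meaningful).
#'
#' @param model A [ude_model()].
#' @param data A `ude_dataset`.
#' @return An object of class `log_density_bundle`: functions
#'   `log_likelihood(theta)`, `log_prior(theta)`, `log_posterior(theta)`,
#'   each accepting `grad = TRUE`, plus `n_params`, `par_names`, and the
#'   model/data.
#' @export
make_log_density <- function(model, data) {
  force(model); force(data)
  ll <- function(theta_u, grad = FALSE)
    log_likelihood(theta_u, data, model, grad = grad)
  lp <- function(theta_u, grad = FALSE) log_prior(theta_u, model, grad = grad)
  lpost <- function(theta_u, grad = FALSE) {
    a <- ll(theta_u, grad = grad)
    b <- lp(theta_u, grad = grad)
    out <- as.numeric(a) + as.numeric(b)
    if (grad)
      attr(out, "gradient") <- attr(a, "gradient") + attr(b, "gradient")
    out
  }
  structure(
    list(log_likelihood = ll, log_prior = lp, log_posterior = lpost,
         n_params = model$n_params, par_names = model$par_names,
         model = model, data = data),
    class = "log_density_bundle"
  )
}
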