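#' Bounded and positive parameter transformations
#'
#' Mechanistic rates are estimated on an unconstrained scale and mapped into
#' their bounds with a tanh transform, `lb + (ub - lb) * (tanh(u) + 1) / 2`;
#' the noise parameter (Gaussian sd or negative-binomial dispersion) uses a
#' log transform, `exp(u)`. Both are smooth strictly increasing bijections,
#' so optimizers and samplers work on all of R while the model only ever
#' sees admissible values.
#'
#' @param u Unconstrained value(s).
#' @param v Constrained value(s), strictly inside `(lb, ub)` for the inverse.
#' @param lb,ub Bounds, `lb < ub`.
#' @return Transformed value(s).
#' @export
transform_mech <- function(u, lb, ub) {
  if (lb >= ub) stop("transform_mech requires lb < ub")
  lb + (ub - lb) * (tanh(u) + 1) / 2
}

#' @rdname transform_mech
#' @export
inverse_transform_mech <- function(v, lb, ub) {
  if (lb >= ub) stop("transform_mech requires lb < ub")
  atanh(2 * (v - lb) / (ub - lb) - 1)
}

# derivative of transform_mech with respect to u (for the chain rule)
dtransform_mech <- function(u, lb, ub) (ub - lb) / 2 * (1 - tanh(u)^2)

#' @rdname transform_mech
#' @export
transform_noise <- function(u) exp(u)

#' @rdname transform_mech
#' @export
inverse_transform_noise <- function(v) {
  if (any(v <= 0)) stop("noise parameter must be positive")
  log(v)
}

#' Define a UDE model: SEIR skeleton with a neural transmission rate
#'
#' Bundles everything the objective needs: the network architecture for
#' beta(t), the (assumed known) initial state and population size, bounds
#' for the mechanistic rates alpha and gamma, the noise model, prior scales,
#' and the fixed-step size of the compiled Runge-Kutta solver. The full
#' parameter vector theta = (theta_mech, theta_net, theta_np) lives in
#' unconstrained space with layout `(u_alpha, u_gamma, net weights..., u_noise)`.
#'
#' @param network A [network_spec()].
#' @param x0 Known initial state `(S, E, I, R)`.
#' @param N Population size.
#' @param bounds List with `alpha` and `gamma` as `(lb, ub)` pairs, per day.
#' @param noise_model `"gaussian"` or `"negbin"`.
#' @param prior List of prior scales: `sd_net` (isotropic Gaussian sd on
#'   network weights), `sd_mech` (sd on unconstrained rates), `mean_noise`,
#'   `sd_noise` (Gaussian on the log noise parameter).
#' @param dt Solver step in days (classical RK4, fixed step).
#' @return An object of class `ude_model`.
#' @export
ude_model <- function(network = network_spec(),
                      x0 = c(S = 0.99, E = 0, I = 0.01, R = 0),
                      N = 1,
                      bounds = list(alpha = c(0, 1), gamma = c(0, 1)),
                      noise_model = c("gaussian", "negbin"),
                      prior = list(sd_net = 1, sd_mech = 1,
                                   mean_noise = log(0.1), sd_noise = 1),
                      dt = 0.1) {
  noise_model <- match.arg(noise_model)
  stopifnot(inherits(network, "network_spec"), length(x0) == 4, all(x0 >= 0),
            N > 0, dt > 0)
  par_names <- c("u_alpha", "u_gamma",
                 paste0("w", seq_len(network$n_params)), "u_noise")
  structure(
    list(network = network, x0 = setNames(as.numeric(x0), c("S", "E", "I", "R")),
         N = N, bounds = bounds, noise_model = noise_model, prior = prior,
         dt = dt, n_params = length(par_names), par_names = par_names),
    class = "ude_model"
  )
}

#' @export
print.ude_model <- function(x, ...) {
  cat(sprintf("UDE model: SEIR + %s-unit beta(t) network, %s noise, %d parameters\n",
              paste(x$network$sizes, collapse = "-"), x$noise_model, x$n_params))
  invisible(x)
}

# index helpers into the flat unconstrained vector
idx_mech <- function(model) 1:2
idx_net <- function(model) 2 + seq_len(model$network$n_params)
idx_noise <- function(model) model$n_params

#' Map an unconstrained parameter vector to constrained values
#'
#' @param theta_u Unconstrained vector of length `model$n_params`.
#' @param model A [ude_model()].
#' @return List with `alpha`, `gamma`, `theta_net`, `noise` (sigma or d).
#' @export
constrain_params <- function(theta_u, model) {
  stopifnot(length(theta_u) == model$n_params)
  b <- model$bounds
  list(
    alpha = transform_mech(theta_u[[1]], b$alpha[1], b$alpha[2]),
    gamma = transform_mech(theta_u[[2]], b$gamma[1], b$gamma[2]),
    theta_net = unname(theta_u[idx_net(model)]),
    noise = transform_noise(theta_u[[idx_noise(model)]])
  )
}

#' @rdname constrain_params
#' @param params List as returned by [constrain_params()].
#' @export
unconstrain_params <- function(params, model) {
  b <- model$bounds
  setNames(
    c(inverse_transform_mech(params$alpha, b$alpha[1], b$alpha[2]),
      inverse_transform_mech(params$gamma, b$gamma[1], b$gamma[2]),
      params$theta_net,
      inverse_transform_noise(params$noise)),
    model$par_names
  )
}

#' Serialize a parameter vector to JSON and back
#'
#' Writes named blocks (unconstrained mechanistic and noise values plus the
#' flat network weight list) so runs can be round-tripped between stages.
#'
#' @param theta_u Unconstrained parameter vector.
#' @param model A [ude_model()].
#' @param path File path.
#' @export
write_params <- function(theta_u, model, path) {
  obj <- list(u_alpha = theta_u[[1]], u_gamma = theta_u[[2]],
              theta_net = unname(theta_u[idx_net(model)]),
              u_noise = theta_u[[idx_noise(model)]])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path, model) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  setNames(c(obj$u_alpha, obj$u_gamma, obj$theta_net, obj$u_noise),
           model$par_names)
}
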