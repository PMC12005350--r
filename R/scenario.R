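#' Specify a synthetic data-generating scenario
#'
#' A scenario bundles everything the generator needs: the compartmental model
#' and its mechanistic rates, the form of the time-varying transmission rate
#' beta(t), the initial state, the observation grid, and the noise model.
#' Two SEIR scenarios are registered by name in [make_scenario()]: a pulse
#' (intervention window) and a waves (oscillating contact rate) form.
#'
#' @param model_name One of `"seir_pulse"`, `"seir_waves"`.
#' @param mech_params Named list/vector with `alpha` (E to I transition rate,
#'   per day), `gamma` (recovery rate, per day) and `N` (population size;
#'   defaults use fractions, N = 1).
#' @param beta_form `"pulse"`, `"waves"`, or `"custom"` (then supply `beta_fn`).
#' @param beta_fn Vectorized function of time, required for `beta_form = "custom"`.
#' @param x0 Initial state `(S, E, I, R)`, non-negative, summing to `N`.
#' @param t_grid Strictly increasing observation times in days.
#' @param noise_model `"gaussian"` (additive, constant sd `sigma`) or
#'   `"negbin"` (counts with mean ybar and dispersion `d`, Var = mu + mu^2/d).
#' @param noise_params Named list: `sigma > 0` for Gaussian, `d > 0` for
#'   negative binomial.
#' @param seed Integer seed used by [observe()] and [make_scenario()].
#' @param solver Control list for the truth integrator: `method` (a
#'   [deSolve::ode()] method, default `"ode45"`), `rtol`, `atol` (default 1e-8,
#'   tight enough that global error stays below 1e-4 over the pulse horizon).
#' @return An object of class `scenario_config`.
#' @seealso [make_scenario()], [simulate_trajectory()], [observe()]
#' @export
scenario_config <- function(model_name = "seir_waves",
                            mech_params = list(alpha = 0.2, gamma = 0.3, N = 1),
                            beta_form = c("waves", "pulse", "custom"),
                            beta_fn = NULL,
                            x0 = c(S = 0.99, E = 0, I = 0.01, R = 0),
                            t_grid = seq(0, 30, length.out = 30),
                            noise_model = c("gaussian", "negbin"),
                            noise_params = list(sigma = 0.01),
                            seed = 1L,
                            solver = list(method = "ode45", rtol = 1e-8, atol = 1e-8)) {
  beta_form <- match.arg(beta_form)
  noise_model <- match.arg(noise_model)
  mech_params <- as.list(mech_params)
  stopifnot(
    all(c("alpha", "gamma", "N") %in% names(mech_params)),
    length(x0) == 4, all(x0 >= 0),
    length(t_grid) >= 1, all(diff(t_grid) > 0)
  )
  if (mech_params$N <= 0) stop("population size N must be positive")
  if (noise_model == "gaussian") {
    if (is.null(noise_params$sigma) || noise_params$sigma <= 0)
      stop("gaussian noise requires sigma > 0")
  } else {
    if (is.null(noise_params$d) || noise_params$d <= 0)
      stop("negbin noise requires dispersion d > 0")
  }
  beta_fn <- switch(beta_form,
    pulse = beta_pulse,
    waves = beta_waves,
    custom = {
      if (!is.function(beta_fn)) stop("beta_form = 'custom' requires beta_fn")
      beta_fn
    }
  )
  # discontinuity times of beta(t); the integrator restarts there
  beta_breaks <- if (beta_form == "pulse") c(15, 30) else numeric(0)
  structure(
    list(
      model_name = model_name, mech_params = mech_params,
      beta_form = beta_form, beta_fn = beta_fn, beta_breaks = beta_breaks,
      x0 = setNames(as.numeric(x0), c("S", "E", "I", "R")),
      t_grid = as.numeric(t_grid), n_obs = length(t_grid),
      noise_model = noise_model, noise_params = noise_params,
      seed = as.integer(seed), solver = solver
    ),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("SEIR scenario config:", x$model_name, "\n")
  cat(sprintf("  beta form: %s; alpha=%.3g gamma=%.3g N=%.3g\n",
              x$beta_form, x$mech_params$alpha, x$mech_params$gamma,
              x$mech_params$N))
  cat(sprintf("  %d observation times on [%.3g, %.3g] days; noise: %s\n",
              x$n_obs, min(x$t_grid), max(x$t_grid), x$noise_model))
  invisible(x)
}

#' SEIR vector field with a time-varying transmission rate
#'
#' Right-hand side of the four-compartment susceptible-exposed-infectious-
#' recovered model: dS = -beta(t) S I / N, dE = beta(t) S I / N - alpha E,
#' dI = alpha E - gamma I, dR = gamma I. The four components telescope to
#' zero, so S + E + I + R is conserved along any trajectory.
#'
#' @param t Time in days.
#' @param x State vector `(S, E, I, R)`, components non-negative.
#' @param alpha,gamma Transition and recovery rates, per day.
#' @param beta_fn Function of time returning the transmission rate.
#' @param N Population size (> 0).
#' @return Derivative 4-vector.
#' @export
seir_rhs <- function(t, x, alpha, gamma, beta_fn, N) {
  if (N <= 0) stop("population size N must be positive")
  b <- beta_fn(t)
  inf <- b * x[[1]] * x[[3]] / N
  c(-inf, inf - alpha * x[[2]], alpha * x[[2]] - gamma * x[[3]],
    gamma * x[[3]])
}

#' Integrate the noiseless truth of a scenario
#'
#' Solves the SEIR equations with the configured beta(t) on the scenario's
#' observation grid using an adaptive-step Runge-Kutta integrator
#' ([deSolve::ode()], Dormand-Prince `ode45` by default). The observable map
#' h selects the infectious and recovered compartments.
#'
#' @param config A [scenario_config()].
#' @return An object of class `trajectory`: list with `times`, `states`
#'   (n_t x 4 matrix), `beta_values`, and `observables` (n_t x 2, columns
#'   `I`, `R`).
#' @export
simulate_trajectory <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  mp <- config$mech_params
  rhs <- function(t, x, parms) {
    list(seir_rhs(t, x, mp$alpha, mp$gamma, config$beta_fn, mp$N))
  }
  times <- config$t_grid
  t_end <- max(times)
  # restart the adaptive solver at beta discontinuities (piecewise solve)
  breaks <- config$beta_breaks %||% numeric(0)
  bounds <- sort(unique(c(0, breaks[breaks > 0 & breaks < t_end], t_end)))
  states <- matrix(NA_real_, length(times), 4)
  x <- config$x0
  for (s in seq_len(length(bounds) - 1)) {
    a <- bounds[s]; b <- bounds[s + 1]
    inner <- times[times > a & times <= b]
    ts <- unique(c(a, inner, b))
    sol <- deSolve::ode(
      y = x, times = ts, func = rhs, parms = NULL,
      method = config$solver$method %||% "ode45",
      rtol = config$solver$rtol %||% 1e-8, atol = config$solver$atol %||% 1e-8
    )
    if (attr(sol, "istate")[1] < 0)
      stop("ODE integration failed for scenario '", config$model_name, "'")
    m <- unname(as.matrix(sol[, 2:5]))
    states[match(inner, times), ] <- m[match(inner, ts), ]
    x <- setNames(m[nrow(m), ], c("S", "E", "I", "R"))
  }
  if (times[1] == 0) states[1, ] <- config$x0
  colnames(states) <- c("S", "E", "I", "R")
  structure(
    list(
      times = times, states = states,
      beta_values = config$beta_fn(times),
      observables = states[, c("I", "R"), drop = FALSE],
      config = config
    ),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("SEIR trajectory: %d time points on [%.3g, %.3g] days\n",
              length(x$times), min(x$times), max(x$times)))
  cat(sprintf("  final state: S=%.4g E=%.4g I=%.4g R=%.4g\n",
              x$states[nrow(x$states), 1], x$states[nrow(x$states), 2],
              x$states[nrow(x$states), 3], x$states[nrow(x$states), 4]))
  invisible(x)
}

#' Corrupt a noiseless trajectory with observation noise
#'
#' Only the infectious (I) and recovered (R) compartments are observed.
#' Gaussian noise adds iid N(0, sigma^2) to each observation; negative
#' binomial noise draws counts with mean ybar and dispersion d under the
#' Var = mu + mu^2/d convention (mu may be any non-negative real). Tiny
#' negative means from solver round-off are clamped to zero before sampling.
#'
#' @param traj A [simulate_trajectory()] result.
#' @param noise_model,noise_params,seed Defaults come from the trajectory's
#'   config; override to re-noise the same truth.
#' @return An object of class `ude_dataset`: `times`, `y` (n_t x 2 matrix),
#'   `observable_names`, `noise_model`, `noise_params`, `split_mask`
#'   (all `"train"` until [split_data()] assigns one), `seed`.
#' @export
observe <- function(traj, noise_model = NULL, noise_params = NULL, seed = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  cfg <- traj$config
  noise_model <- noise_model %||% cfg$noise_model
  noise_params <- noise_params %||% cfg$noise_params
  seed <- seed %||% cfg$seed
  ybar <- traj$observables
  n <- length(ybar)
  y <- withr::with_seed(seed, {
    if (noise_model == "gaussian") {
      sigma <- noise_params$sigma
      if (is.null(sigma) || sigma <= 0) stop("sigma must be > 0")
      ybar + rnorm(n, sd = sigma)
    } else if (noise_model == "negbin") {
      d <- noise_params$d
      if (is.null(d) || d <= 0) stop("dispersion d must be > 0")
      mu <- pmax(ybar, 0)
      matrix(rnbinom(n, size = d, mu = mu), nrow = nrow(ybar))
    } else stop("unknown noise model: ", noise_model)
  })
  dimnames(y) <- list(NULL, c("I", "R"))
  structure(
    list(
      times = traj$times, y = y, observable_names = c("I", "R"),
      noise_model = noise_model, noise_params = noise_params,
      split_mask = rep("train", nrow(y)), seed = as.integer(seed)
    ),
    class = "ude_dataset"
  )
}

#' @export
print.ude_dataset <- function(x, ...) {
  cat(sprintf("UDE dataset: %d time points x %d observables (%s noise)\n",
              nrow(x$y), ncol(x$y), x$noise_model))
  invisible(x)
}

#' One-call generation of a registered scenario
#'
#' Builds the config, integrates the truth, and draws noisy observations of
#' I and R at 30 time points (the default grid). Deterministic given the seed.
#'
#' @param name `"seir_pulse"` (t in \[0, 60\], so the 15-30 day intervention
#'   window is interior) or `"seir_waves"` (t in \[0, 30\]).
#' @param ... Overrides passed to [scenario_config()] (e.g. `noise_model`,
#'   `noise_params`, `seed`, `t_grid`).
#' @return List with `config`, `trajectory`, `dataset`.
#' @examples
#' sc <- make_scenario("seir_waves", seed = 42)
#' nrow(sc$dataset$y)  # 30
#' @export
make_scenario <- function(name = c("seir_waves", "seir_pulse"), ...) {
  name <- match.arg(name)
  defaults <- switch(name,
    seir_waves = list(model_name = "seir_waves", beta_form = "waves",
                      t_grid = seq(0, 30, length.out = 30)),
    seir_pulse = list(model_name = "seir_pulse", beta_form = "pulse",
                      t_grid = seq(0, 60, length.out = 30))
  )
  overrides <- list(...)
  args <- utils::modifyList(defaults, overrides)
  config <- do.call(scenario_config, args)
  traj <- simulate_trajectory(config)
  list(config = config, trajectory = traj, dataset = observe(traj))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
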