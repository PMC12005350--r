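# Independent oracles used across the suite. These deliberately avoid the
# package's own solvers and densities.

# fixed-step classical RK4 integrator over an arbitrary rhs(t, x) -> dx
rk4_oracle <- function(rhs, x0, times, dt) {
  out <- matrix(NA_real_, length(times), length(x0))
  x <- x0
  t <- times[1]
  out[1, ] <- x
  for (k in 2:length(times)) {
    span <- times[k] - t
    n <- max(1L, ceiling(span / dt - 1e-9))
    h <- span / n
    for (s in seq_len(n)) {
      k1 <- rhs(t, x)
      k2 <- rhs(t + h / 2, x + h / 2 * k1)
      k3 <- rhs(t + h / 2, x + h / 2 * k2)
      k4 <- rhs(t + h, x + h * k3)
      x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    t <- times[k]
    out[k, ] <- x
  }
  out
}

# scalar Gaussian log-density from first principles
normal_logpdf_oracle <- function(y, mu, sigma) {
  -0.5 * log(2 * pi) - log(sigma) - (y - mu)^2 / (2 * sigma^2)
}

# negative binomial log-pmf (mean mu, dispersion d; Var = mu + mu^2/d)
# written directly from the Gamma-function form of the pmf
negbin_logpmf_oracle <- function(y, mu, d) {
  lgamma(y + d) - lgamma(d) - lgamma(y + 1) +
    d * log(d / (d + mu)) + y * log(mu / (d + mu))
}

# dense tanh MLP evaluated with explicit matrix algebra (weights given as
# per-layer matrices, independently of the package's flattening)
mlp_oracle <- function(x, Ws, bs, beta_max) {
  a <- x
  L <- length(Ws)
  for (l in seq_len(L)) {
    z <- Ws[[l]] %*% a + bs[[l]]
    a <- if (l < L) tanh(z) else z
  }
  beta_max * (tanh(a[1, 1]) + 1) / 2
}

# central finite differences of a scalar function
fd_gradient <- function(f, x, h = 1e-5, idx = seq_along(x)) {
  vapply(idx, function(j) {
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# a small model used by many tests: narrow network keeps solves fast
small_model <- function(dt = 0.25, width = 4, noise_model = "gaussian",
                        t_max = 30) {
  ude_model(network = network_spec(n_hidden = 2, width = width, t_max = t_max),
            noise_model = noise_model, dt = dt)
}

random_theta <- function(model, seed = 1, scale = 0.3) {
  withr::with_seed(seed,
    setNames(rnorm(model$n_params, 0, scale), model$par_names))
}
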