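test_that("bounded and positive transforms are exact bijections", {
  expect_equal(transform_mech(0, 0, 1), 0.5)
  expect_equal(transform_mech(30, 0, 1), 1, tolerance = 1e-12)
  expect_equal(transform_mech(-30, 0, 1), 0, tolerance = 1e-12)
  expect_lt(abs(inverse_transform_mech(transform_mech(1.3, 0, 2), 0, 2) - 1.3),
            1e-10)
  u <- seq(-3, 3, length.out = 50)
  v <- transform_mech(u, 0.1, 0.9)
  expect_true(all(diff(v) > 0))
  expect_true(all(v > 0.1 & v < 0.9))
  expect_error(transform_mech(0, 1, 1), "lb < ub")

  expect_equal(transform_noise(0), 1)
  expect_lt(abs(transform_noise(-4.60517) - 0.01), 1e-6)
  x <- c(-2, 0.5, 3)
  expect_equal(log(transform_noise(x)), x)
  expect_equal(inverse_transform_noise(transform_noise(x)), x)
})

test_that("constrain/unconstrain round-trips the full parameter vector", {
  model <- small_model()
  theta <- random_theta(model, seed = 4)
  cp <- constrain_params(theta, model)
  expect_true(cp$alpha > 0 && cp$alpha < 1 && cp$gamma > 0 && cp$gamma < 1)
  expect_gt(cp$noise, 0)
  back <- unconstrain_params(cp, model)
  expect_equal(unname(back), unname(theta), tolerance = 1e-10)
})

test_that("parameter vectors round-trip through JSON", {
  model <- small_model()
  theta <- random_theta(model, seed = 9)
  path <- file.path(tempdir(), "params.json")
  write_params(theta, model, path)
  expect_equal(unname(read_params(path, model)), unname(theta),
               tolerance = 1e-12)
  unlink(path)
})

test_that("network output is bounded and matches a matrix-algebra oracle", {
  spec <- network_spec(n_hidden = 1, width = 2, beta_max = 0.8, t_max = 10)
  # hand-set weights: W1 = [[0.5], [-1]], b1 = (0.1, 0.2), W2 = [0.3, -0.4], b2 = 0.05
  theta <- c(0.5, -1, 0.1, 0.2, 0.3, -0.4, 0.05)
  expect_equal(length(theta), spec$n_params)
  for (t in c(0, 2.5, 7, 10)) {
    want <- mlp_oracle(matrix(t / 10), list(matrix(c(0.5, -1), 2, 1),
                                            matrix(c(0.3, -0.4), 1, 2)),
                       list(c(0.1, 0.2), 0.05), beta_max = 0.8)
    expect_equal(network_beta(t, theta, spec), want, tolerance = 1e-12)
  }
  # zero parameters give the midpoint rate everywhere
  spec2 <- network_spec(n_hidden = 2, width = 10, beta_max = 1, t_max = 30)
  expect_equal(network_beta(c(0, 7, 30), rep(0, spec2$n_params), spec2),
               rep(0.5, 3))
  # any parameters stay strictly inside (0, beta_max)
  for (s in 1:5) {
    th <- withr::with_seed(s, rnorm(spec2$n_params, sd = 2))
    v <- network_beta(seq(0, 30, by = 1), th, spec2)
    expect_true(all(v > 0 & v < 1))
  }
  expect_error(network_beta(1, rep(0, 3), spec), "length")
})

test_that("UDE forward solve reduces to the constant-beta SEIR and conserves", {
  model <- small_model(dt = 0.1)
  theta <- random_theta(model, seed = 2)
  theta[idx_net <- 2 + seq_len(model$network$n_params)] <- 0  # beta = 0.5
  tg <- seq(0, 30, length.out = 30)
  fw <- solve_forward(theta, model, tg)
  cp <- constrain_params(theta, model)
  rhs <- function(t, x) seir_rhs(t, x, cp$alpha, cp$gamma, function(t) 0.5, 1)
  oracle <- rk4_oracle(rhs, model$x0, c(0, tg), dt = 1e-3)[-1, ]
  expect_lt(max(abs(fw$states - oracle)), 1e-4)
  expect_lt(max(abs(rowSums(fw$states) - 1)), 1e-6)
  expect_equal(fw$beta, rep(0.5, length(tg)))
  # degenerate grid: only t0 -> the observables are h(x0)
  fw0 <- solve_forward(theta, model, 0)
  expect_equal(unname(fw0$yhat[1, ]), unname(model$x0[c("I", "R")]))
})

test_that("compiled network inside the solver matches the R evaluation", {
  model <- small_model(dt = 0.25)
  theta <- random_theta(model, seed = 11, scale = 0.8)
  tg <- seq(0, 30, by = 3)
  fw <- solve_forward(theta, model, tg)
  expect_equal(fw$beta,
               network_beta(tg, constrain_params(theta, model)$theta_net,
                            model$network),
               tolerance = 1e-12)
})

test_that("sensitivity gradient of the log-likelihood matches finite differences", {
  model <- small_model(dt = 0.25)
  sc <- make_scenario("seir_waves", seed = 3,
                      t_grid = seq(0, 30, length.out = 10))
  theta <- random_theta(model, seed = 5)
  ll <- log_likelihood(theta, sc$dataset, model, grad = TRUE)
  g <- attr(ll, "gradient")
  expect_true(all(is.finite(g)))
  idx <- c(1, 2, 3, 7, 20, model$n_params)
  fd <- fd_gradient(function(th)
    as.numeric(log_likelihood(th, sc$dataset, model)), theta, idx = idx)
  expect_lt(max(abs(g[idx] - fd) / pmax(abs(fd), 1e-6)), 1e-4)
})

test_that("negative-binomial likelihood and gradient match the Gamma oracle", {
  model <- small_model(dt = 0.25, noise_model = "negbin")
  sc <- make_scenario("seir_waves", seed = 4, noise_model = "negbin",
                      noise_params = list(d = 5),
                      mech_params = list(alpha = 0.2, gamma = 0.3, N = 1000),
                      x0 = c(990, 0, 10, 0),
                      t_grid = seq(0, 30, length.out = 8))
  model$N <- 1000
  model$x0 <- c(S = 990, E = 0, I = 10, R = 0)
  theta <- random_theta(model, seed = 6, scale = 0.2)
  ll <- log_likelihood(theta, sc$dataset, model, grad = TRUE)
  # oracle: sum of Gamma-function log-pmfs at the model's own predictions
  fw <- solve_forward(theta, model, sc$dataset$times)
  d <- transform_noise(theta[[model$n_params]])
  want <- sum(negbin_logpmf_oracle(sc$dataset$y, pmax(fw$yhat, 1e-10), d))
  expect_equal(as.numeric(ll), want, tolerance = 1e-10)
  # pointwise identity at y = 0: log pmf = d * log(d / (d + mu))
  expect_equal(negbin_logpmf_oracle(0, 3.7, d), d * log(d / (d + 3.7)))
  idx <- c(1, 2, 10, model$n_params)
  fd <- fd_gradient(function(th)
    as.numeric(log_likelihood(th, sc$dataset, model)), theta, idx = idx)
  expect_lt(max(abs(attr(ll, "gradient")[idx] - fd) / pmax(abs(fd), 1e-6)),
            1e-4)
})

test_that("zero-residual Gaussian likelihood attains its analytic value", {
  model <- small_model(dt = 0.25)
  theta <- random_theta(model, seed = 7)
  tg <- seq(0, 30, length.out = 12)
  fw <- solve_forward(theta, model, tg)
  sigma <- transform_noise(theta[[model$n_params]])
  data <- structure(list(times = tg, y = fw$yhat,
                         observable_names = c("I", "R"),
                         noise_model = "gaussian",
                         noise_params = list(sigma = sigma),
                         split_mask = rep("train", length(tg)), seed = 1L),
                    class = "ude_dataset")
  n <- length(data$y)
  expect_equal(as.numeric(log_likelihood(theta, data, model)),
               -(n / 2) * log(2 * pi * sigma^2), tolerance = 1e-10)
  # and equals the sum of scalar normal log-pdf oracles on a 3-point toy
  data3 <- data
  data3$times <- tg[1:3]
  data3$y <- fw$yhat[1:3, ] + 0.05
  data3$split_mask <- rep("train", 3)
  expect_equal(as.numeric(log_likelihood(theta, data3, model)),
               sum(normal_logpdf_oracle(data3$y, fw$yhat[1:3, ], sigma)),
               tolerance = 1e-10)
})

test_that("log-prior decomposes into per-block Gaussian oracles", {
  model <- small_model()
  theta <- random_theta(model, seed = 8)
  lp <- log_prior(theta, model, grad = TRUE)
  pr <- model$prior
  nw <- model$network$n_params
  want <- sum(normal_logpdf_oracle(theta[1:2], 0, pr$sd_mech)) +
    sum(normal_logpdf_oracle(theta[2 + seq_len(nw)], 0, pr$sd_net)) +
    normal_logpdf_oracle(theta[[model$n_params]], pr$mean_noise, pr$sd_noise)
  expect_equal(as.numeric(lp), want, tolerance = 1e-12)
  # zero network weights: network block contributes its mode density
  theta0 <- theta; theta0[2 + seq_len(nw)] <- 0
  lp0 <- as.numeric(log_prior(theta0, model))
  expect_equal(lp0 - as.numeric(log_prior(theta, model)),
               -sum(normal_logpdf_oracle(theta[2 + seq_len(nw)], 0, pr$sd_net)) +
                 nw * normal_logpdf_oracle(0, 0, pr$sd_net), tolerance = 1e-10)
  fd <- fd_gradient(function(th) as.numeric(log_prior(th, model)), theta,
                    idx = c(1, 5, model$n_params))
  expect_equal(attr(lp, "gradient")[c(1, 5, model$n_params)], fd,
               tolerance = 1e-6)
})

test_that("posterior differences are invariant to the evidence constant", {
  model <- small_model(dt = 0.25)
  sc <- make_scenario("seir_waves", seed = 10,
                      t_grid = seq(0, 30, length.out = 8))
  bundle <- make_log_density(model, sc$dataset)
  th1 <- random_theta(model, seed = 1)
  th2 <- random_theta(model, seed = 2)
  lhs <- bundle$log_posterior(th1) - bundle$log_posterior(th2)
  rhs <- (as.numeric(bundle$log_likelihood(th1)) + as.numeric(bundle$log_prior(th1))) -
    (as.numeric(bundle$log_likelihood(th2)) + as.numeric(bundle$log_prior(th2)))
  expect_equal(as.numeric(lhs), rhs, tolerance = 1e-10)
  # posterior gradient is the sum of the blocks' gradients
  g <- attr(bundle$log_posterior(th1, grad = TRUE), "gradient")
  g2 <- attr(bundle$log_likelihood(th1, grad = TRUE), "gradient") +
    attr(bundle$log_prior(th1, grad = TRUE), "gradient")
  expect_equal(g, g2, tolerance = 1e-12)
})

test_that("mismatched noise models are rejected and failures yield -Inf", {
  model <- small_model(noise_model = "negbin")
  sc <- make_scenario("seir_waves", seed = 3)
  expect_error(log_likelihood(random_theta(model), sc$dataset, model),
               "noise model")
  # a parameter vector driving the solver to explosion returns the sentinel
  model_g <- small_model(dt = 0.25)
  model_g$N <- 1e-300  # pathological config to force non-finite states
  theta <- random_theta(model_g, seed = 1, scale = 1)
  ll <- log_likelihood(theta, sc$dataset, model_g, grad = TRUE)
  expect_identical(as.numeric(ll), -Inf)
  expect_identical(attr(ll, "gradient"), rep(0, model_g$n_params))
})
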