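# toy targets used throughout: densities with closed-form moments
std_normal_target <- function(d) {
  function(theta, grad = FALSE) {
    out <- -0.5 * sum(theta^2) - d / 2 * log(2 * pi)
    if (grad) attr(out, "gradient") <- -theta
    out
  }
}

test_that("NUTS recovers a two-dimensional standard normal", {
  target <- std_normal_target(2)
  inits <- list(c(2, -2), c(-2, 2), c(1, 1), c(-1, -1))
  cs <- run_nuts(target, inits, n_samples = 1000, n_warmup = 500, seed = 42)
  flat <- apply(cs$draws, 3, identity)  # (chains*samples) x 2
  n_eff <- min(cs$diagnostics$ess)
  expect_gt(n_eff, 100)
  for (j in 1:2) {
    expect_lt(abs(mean(flat[, j])), 3 / sqrt(n_eff))
    expect_lt(abs(sd(flat[, j]) - 1), 0.05)
  }
  expect_lt(max(cs$diagnostics$rhat), 1.05)
})

test_that("NUTS is deterministic given the seed", {
  target <- std_normal_target(2)
  a <- run_nuts(target, list(c(0, 0)), n_samples = 100, n_warmup = 100, seed = 7)
  b <- run_nuts(target, list(c(0, 0)), n_samples = 100, n_warmup = 100, seed = 7)
  expect_identical(a$draws, b$draws)
})

test_that("independent target blocks stay uncorrelated under NUTS", {
  target <- std_normal_target(4)
  cs <- run_nuts(target, list(rep(0.5, 4), rep(-0.5, 4)),
                 n_samples = 1000, n_warmup = 500, seed = 3)
  flat <- apply(cs$draws, 3, identity)
  r <- cor(flat[, 1], flat[, 3])
  expect_lt(abs(r), 0.1)
})

test_that("tempering swap rule matches an exact-sampling oracle", {
  # flat target: both chains always hold equal log densities, so every swap
  # proposal has exponent zero and must be accepted
  flat <- function(theta, grad = FALSE) 0
  pt0 <- run_parallel_tempering(flat, init = 0, ladder = c(1, 10),
                                n_samples = 500, n_burn = 100,
                                swap_every = 2, seed = 8)
  expect_equal(unname(pt0$swap_acceptance), 1)

  # Gaussian target N(0,1): the T-tempered stationary law is N(0, T).
  # Oracle: average min(1, exp((1/T1 - 1/T2)(lp(x2) - lp(x1)))) over exact
  # independent draws from the two stationary laws; the sampler's recorded
  # swap rate must agree within Monte-Carlo error.
  t2 <- 4
  lp <- function(x) -0.5 * x^2
  oracle <- withr::with_seed(6, {
    x1 <- rnorm(2e5, 0, 1)
    x2 <- rnorm(2e5, 0, sqrt(t2))
    mean(pmin(1, exp((1 - 1 / t2) * (lp(x2) - lp(x1)))))
  })
  target <- function(theta, grad = FALSE) lp(theta)
  pt <- run_parallel_tempering(target, init = 0, ladder = c(1, t2),
                               n_samples = 20000, n_burn = 5000,
                               swap_every = 2, seed = 13)
  expect_lt(abs(pt$swap_acceptance[1] - oracle), 0.03)
})

bimodal_target <- function(mu = 5, s = 0.5) {
  function(theta, grad = FALSE) {
    out <- log(0.5 * dnorm(theta, -mu, s) + 0.5 * dnorm(theta, mu, s))
    if (grad) attr(out, "gradient") <-
        numeric(1)  # gradient unused by the tempering sampler
    out
  }
}

test_that("tempering crosses modes that trap a single chain", {
  target <- bimodal_target()
  pt <- run_parallel_tempering(target, init = -5,
                               ladder = exp(seq(0, log(50), length.out = 6)),
                               n_samples = 10000, n_burn = 10000,
                               swap_every = 10, seed = 1)
  draws <- pt$draws[1, , 1]
  expect_gt(mean(draws > 2), 0.05)   # reaches the +5 mode
  expect_gt(mean(draws < -2), 0.05)  # and still visits the -5 mode
  expect_true(all(pt$swap_acceptance >= 0 & pt$swap_acceptance <= 1))
  # an untempered chain with the same budget stays in its starting mode
  single <- run_parallel_tempering(target, init = -5, ladder = 1,
                                   n_samples = 10000, n_burn = 10000, seed = 1)
  expect_lt(mean(single$draws[1, , 1] > 2), 0.001)
})

test_that("a one-rung ladder reduces to plain adaptive Metropolis", {
  target <- std_normal_target(1)
  one <- run_parallel_tempering(target, init = 0, ladder = 1,
                                n_samples = 4000, n_burn = 2000, seed = 9)
  expect_null(one$swap_acceptance)
  draws <- one$draws[1, , 1]
  expect_lt(abs(mean(draws)), 0.15)
  expect_lt(abs(sd(draws) - 1), 0.15)
  expect_error(run_parallel_tempering(target, 0, ladder = c(2, 4)),
               "temperature 1")
  expect_error(run_parallel_tempering(target, 0, ladder = c(1, 3, 2)),
               "increasing")
})

test_that("within-chain kernel leaves a three-component target invariant", {
  # binned stationary frequencies of adaptive Metropolis on a mixture must
  # match the target measure (a detailed-balance consequence)
  w <- c(0.2, 0.5, 0.3)
  mu <- c(-4, 0, 4)
  target <- function(theta, grad = FALSE)
    log(sum(w * dnorm(theta, mu, 0.6)))
  pt <- run_parallel_tempering(target, init = 0,
                               ladder = c(1, 3, 9),
                               n_samples = 20000, n_burn = 5000,
                               swap_every = 5, seed = 4)
  draws <- pt$draws[1, , 1]
  freq <- c(mean(draws < -2), mean(abs(draws) <= 2), mean(draws > 2))
  expect_lt(max(abs(freq - w)), 0.05)
})

test_that("conjugate Gaussian posterior is recovered by both samplers", {
  # y_i ~ N(theta, s^2), theta ~ N(0, 1): posterior N(m_post, v_post)
  y <- withr::with_seed(2, rnorm(20, 1.5, 0.7))
  s <- 0.7
  v_post <- 1 / (1 + length(y) / s^2)
  m_post <- v_post * sum(y) / s^2
  target <- function(theta, grad = FALSE) {
    out <- -0.5 * theta^2 + sum(dnorm(y, theta, s, log = TRUE))
    if (grad) attr(out, "gradient") <- -theta + sum(y - theta) / s^2
    out
  }
  cs <- run_nuts(target, list(0, 1), n_samples = 1500, n_warmup = 750, seed = 11)
  draws <- as.vector(cs$draws[, , 1])
  expect_lt(abs(mean(draws) - m_post), 4 * sqrt(v_post / min(cs$diagnostics$ess)))
  expect_lt(abs(sd(draws) - sqrt(v_post)) / sqrt(v_post), 0.1)
  pt <- run_parallel_tempering(target, init = 0, ladder = c(1, 5),
                               n_samples = 8000, n_burn = 4000, seed = 12)
  pdraws <- pt$draws[1, , 1]
  expect_lt(abs(mean(pdraws) - m_post), 0.1 * sqrt(v_post) + 0.05)
  expect_lt(abs(sd(pdraws) - sqrt(v_post)) / sqrt(v_post), 0.15)
})

test_that("optimization endpoints seed the chains best-first", {
  model <- small_model()
  mk <- function(nll, seed) {
    structure(list(final_params = random_theta(model, seed = seed),
                   full_nll = nll, converged = TRUE),
              class = "ensemble_member")
  }
  res <- structure(list(members = list(mk(5, 1), mk(1, 2), mk(3, 3)),
                        best = NULL), class = "ensemble_result")
  inits <- init_from_optimization(res, n_chains = 2)
  expect_length(inits, 2)
  expect_identical(inits[[1]], res$members[[2]]$final_params)
  expect_identical(inits[[2]], res$members[[3]]$final_params)
  # recycling with jitter when members are scarce
  res1 <- structure(list(members = list(mk(5, 1))), class = "ensemble_result")
  expect_message(j4 <- init_from_optimization(res1, n_chains = 4, seed = 2),
                 "recycling")
  expect_length(j4, 4)
  expect_true(all(vapply(j4, function(x) all(is.finite(x)), logical(1))))
  expect_false(identical(j4[[1]], j4[[2]]))
})

test_that("posterior bands thin draws and keep band semantics", {
  model <- small_model(dt = 0.25)
  d <- model$n_params
  draws <- array(NA_real_, c(2, 50, d))
  for (c in 1:2) for (i in 1:50)
    draws[c, i, ] <- random_theta(model, seed = 100 * c + i, scale = 0.2)
  cs <- udeuq:::new_chain_set(draws, matrix(0, 2, 50), algo = "pt")
  tg <- seq(0, 30, length.out = 8)
  b <- posterior_bands(cs, model, tg, thin = 40, level = 0.9)
  expect_equal(b$n_draws, 40)
  expect_true(all(b$lower <= b$upper))
  bn <- posterior_bands(cs, model, tg, thin = 40, level = 0.9,
                        include_noise = TRUE)
  expect_true(mean((bn$upper[, "obs_I"] - bn$lower[, "obs_I"]) -
                     (b$upper[, "obs_I"] - b$lower[, "obs_I"])) > 0)
})
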