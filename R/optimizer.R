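# First-order adaptive optimizer (Adam). fn(theta) must return the objective
# to MINIMIZE with its gradient in attr "gradient". Used by ensemble training
# and by the stochastic ELBO ascent (with sign flipped by the caller).
adam_minimize <- function(theta0, fn, n_iter, lr = 1e-2,
                          beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                          callback = NULL) {
  theta <- theta0
  m <- v <- numeric(length(theta0))
  for (it in seq_len(n_iter)) {
    val <- fn(theta)
    g <- attr(val, "gradient")
    if (!all(is.finite(g))) g[!is.finite(g)] <- 0
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^it)
    vhat <- v / (1 - beta2^it)
    theta <- theta - lr * mhat / (sqrt(vhat) + eps)
    if (!is.null(callback) && isTRUE(callback(it, theta, as.numeric(val))))
      break
  }
  theta
}
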