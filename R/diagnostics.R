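# Split R-hat (potential scale reduction) over an n_chains x n_samples x 1
# slice: each chain is split in half, then the usual between/within variance
# ratio is computed over the 2*n_chains half-chains.
split_rhat <- function(x) {
  dm <- dim(x)
  n <- dm[2] %/% 2
  if (n < 2) return(NA_real_)
  halves <- list()
  for (c in seq_len(dm[1])) {
    halves[[2 * c - 1]] <- x[c, 1:n, 1]
    halves[[2 * c]] <- x[c, (n + 1):(2 * n), 1]
  }
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Effective sample size: per chain, autocorrelations are accumulated with
# Geyer's initial positive-sequence truncation; chain ESS values are summed.
ess_basic <- function(x) {
  dm <- dim(x)
  total <- 0
  for (c in seq_len(dm[1])) {
    v <- x[c, , 1]
    n <- length(v)
    if (sd(v) == 0 || n < 4) { total <- total + 1; next }
    rho <- as.numeric(acf(v, lag.max = min(n - 2, 200), plot = FALSE,
                          demean = TRUE)$acf)[-1]
    s <- 0; k <- 1
    while (k + 1 <= length(rho)) {
      pair <- rho[k] + rho[k + 1]
      if (pair < 0) break
      s <- s + pair
      k <- k + 2
    }
    total <- total + n / (1 + 2 * s)
  }
  total
}
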