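#' Architecture of the transmission-rate network
#'
#' The time-varying transmission rate beta(t) is modelled by a small
#' feed-forward network: scalar input t / t_max (time scaled to roughly
#' \[0, 1\]), `n_hidden` tanh layers of `width` units, and a linear output
#' squashed to (0, beta_max) via `beta_max * (tanh(z) + 1) / 2`, so the rate
#' is bounded by construction.
#'
#' @param n_hidden Number of hidden layers (default 2).
#' @param width Units per hidden layer (default 10).
#' @param beta_max Upper bound of the output rate, per day (default 1).
#' @param t_max Time scale used to normalize the input, days.
#' @return An object of class `network_spec` with the layer size vector and
#'   total parameter count `n_params`.
#' @export
network_spec <- function(n_hidden = 2, width = 10, beta_max = 1, t_max = 30) {
  stopifnot(n_hidden >= 1, width >= 1, beta_max > 0, t_max > 0)
  sizes <- c(1L, rep(as.integer(width), n_hidden), 1L)
  n_params <- sum(sizes[-1] * sizes[-length(sizes)] + sizes[-1])
  structure(
    list(sizes = sizes, n_hidden = n_hidden, width = width,
         beta_max = beta_max, t_max = t_max, activation = "tanh",
         n_params = n_params),
    class = "network_spec"
  )
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("beta(t) network: %s tanh MLP, %d parameters, output in (0, %g)\n",
              paste(x$sizes, collapse = "-"), x$n_params, x$beta_max))
  invisible(x)
}

# split a flat weight vector into per-layer W (out x in) and b blocks
net_layers <- function(theta_net, spec) {
  sizes <- spec$sizes
  L <- length(sizes) - 1
  if (length(theta_net) != spec$n_params)
    stop(sprintf("theta_net has length %d but the network spec implies %d",
                 length(theta_net), spec$n_params))
  out <- vector("list", L)
  off <- 0
  for (l in seq_len(L)) {
    nin <- sizes[l]; nout <- sizes[l + 1]
    W <- matrix(theta_net[off + seq_len(nin * nout)], nrow = nout)
    off <- off + nin * nout
    b <- theta_net[off + seq_len(nout)]
    off <- off + nout
    out[[l]] <- list(W = W, b = b)
  }
  out
}

#' Evaluate the transmission-rate network
#'
#' Pure-R forward pass (vectorized over `t`). The compiled solver evaluates
#' the identical architecture internally; this function serves prediction,
#' band construction for beta(t), and as a cross-check of the compiled path.
#'
#' @param t Times in days.
#' @param theta_net Flat weight/bias vector (length `spec$n_params`).
#' @param spec A [network_spec()].
#' @return Transmission rate(s) in (0, beta_max).
#' @export
network_beta <- function(t, theta_net, spec) {
  layers <- net_layers(theta_net, spec)
  L <- length(layers)
  a <- matrix(t / spec$t_max, nrow = 1)
  for (l in seq_len(L)) {
    z <- layers[[l]]$W %*% a + layers[[l]]$b
    a <- if (l < L) tanh(z) else z
  }
  as.numeric(spec$beta_max * (tanh(a) + 1) / 2)
}

# Glorot-style initial weights; biases zero. Used by tests and examples;
# ensemble initializations are drawn from the prior instead.
init_theta_net <- function(spec, seed = NULL, scale = 1) {
  draw <- function() {
    sizes <- spec$sizes
    L <- length(sizes) - 1
    unlist(lapply(seq_len(L), function(l) {
      nin <- sizes[l]; nout <- sizes[l + 1]
      c(rnorm(nin * nout, sd = scale * sqrt(2 / (nin + nout))), rep(0, nout))
    }))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
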