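#' Time-varying transmission rates of the synthetic SEIR scenarios
#'
#' `beta_pulse()` is a piecewise-constant transmission rate emulating a
#' time-restricted intervention: it drops from 0.5/day to 0.05/day strictly
#' inside the window 15 < t < 30 days. `beta_waves()` is a smooth oscillation,
#' `0.3 * cos((-1 + sqrt(1 + 4t)) * 1.5 + 0.25 * pi) + 0.4`, emulating complex
#' time-dependent contact behaviour; its image lies in \[0.1, 0.7\].
#'
#' @param t Time in days. Vectorized. `beta_waves()` requires `t >= 0`.
#' @return Transmission rate(s) per day.
#' @examples
#' beta_pulse(c(0, 20, 40))
#' beta_waves(0)
#' @export
beta_pulse <- function(t) {
  stopifnot(is.numeric(t), all(is.finite(t)))
  ifelse(t > 15 & t < 30, 0.05, 0.5)
}

#' @rdname beta_pulse
#' @export
beta_waves <- function(t) {
  stopifnot(is.numeric(t), all(is.finite(t)))
  if (any(t < 0)) stop("beta_waves() is defined for t >= 0 only")
  0.3 * cos((-1 + sqrt(1 + 4 * t)) * 1.5 + 0.25 * pi) + 0.4
}
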