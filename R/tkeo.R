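#' Discrete Teager-Kaiser energy operator
#'
#' For a sampled signal g\[n\] the operator is
#' \deqn{\Psi(g[n]) = g[n]^2 - g[n-1]\,g[n+1],}
#' a three-sample estimate of instantaneous energy that tracks both
#' amplitude and frequency; for a pure tone `A*cos(w*n)` the interior
#' values are the constant `A^2 sin(w)^2`. The two boundary samples,
#' where the operator is undefined, replicate the nearest interior value.
#'
#' @param signal Numeric vector, length >= 3, all values finite.
#'
#' @return A `tkeo_series`: list with `values` (same length as the input)
#'   and `valid_range` (first and last interior index).
#' @export
tkeo_discrete <- function(signal) {
  if (!is.numeric(signal) || length(signal) < 3L) {
    stop("`signal` must be a numeric vector of length >= 3", call. = FALSE)
  }
  if (!all(is.finite(signal))) stop("`signal` must be finite", call. = FALSE)
  n <- length(signal)
  values <- numeric(n)
  interior <- 2:(n - 1L)
  values[interior] <- signal[interior]^2 -
    signal[interior - 1L] * signal[interior + 1L]
  values[1L] <- values[2L]
  values[n] <- values[n - 1L]
  structure(list(values = values, valid_range = c(2L, n - 1L)),
            class = "tkeo_series")
}

#' Continuous Teager-Kaiser energy operator on a sampled signal
#'
#' Estimates \deqn{\Psi(g(t)) = \dot g(t)^2 - g(t)\,\ddot g(t)} using
#' second-order central finite differences; for `g(t) = A*cos(W*t)` this
#' converges to `A^2 W^2` as `dt -> 0`. Boundary samples replicate the
#' nearest interior value.
#'
#' @param signal Numeric vector, length >= 5.
#' @param dt Sampling interval in seconds (> 0).
#'
#' @return A `tkeo_series` (see [tkeo_discrete()]).
#' @export
tkeo_continuous <- function(signal, dt) {
  if (!is.numeric(signal) || length(signal) < 5L) {
    stop("`signal` must be a numeric vector of length >= 5", call. = FALSE)
  }
  assert_scalar_number(dt, "dt", 0, strict = TRUE)
  if (!all(is.finite(signal))) stop("`signal` must be finite", call. = FALSE)
  n <- length(signal)
  i <- 2:(n - 1L)
  d1 <- (signal[i + 1L] - signal[i - 1L]) / (2 * dt)
  d2 <- (signal[i + 1L] - 2 * signal[i] + signal[i - 1L]) / dt^2
  values <- numeric(n)
  values[i] <- d1^2 - signal[i] * d2
  values[1L] <- values[2L]
  values[n] <- values[n - 1L]
  structure(list(values = values, valid_range = c(2L, n - 1L)),
            class = "tkeo_series")
}
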