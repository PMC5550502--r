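#' Uniformly sampled signal
#'
#' Container for a uniformly sampled time series (position in metres or force
#' in newtons). All operators in the package consume and return this class.
#'
#' @param values numeric vector of samples.
#' @param dt sampling interval in seconds (default 1/400, the 400 Hz
#'   acquisition rate of the tracking rig).
#' @param t0 time of the first sample in seconds.
#' @return An object of class `sampled_signal`.
#' @export
sampled_signal <- function(values, dt = 1 / 400, t0 = 0) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("a sampled_signal needs at least 2 samples")
  if (!is.finite(dt) || dt <= 0) stop("dt must be a positive number")
  structure(list(values = values, dt = dt, t0 = t0),
            class = "sampled_signal")
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<sampled_signal> %d samples @ %.6g Hz, t = [%.4g, %.4g] s\n",
              length(x$values), 1 / x$dt, x$t0,
              x$t0 + (length(x$values) - 1L) * x$dt))
  invisible(x)
}

#' @export
length.sampled_signal <- function(x) length(x$values)

#' Time stamps of a sampled signal
#' @param x a `sampled_signal`.
#' @return numeric vector of sample times in seconds.
#' @export
signal_time <- function(x) {
  stopifnot(inherits(x, "sampled_signal"))
  x$t0 + (seq_along(x$values) - 1L) * x$dt
}

as_signal_like <- function(values, template) {
  sampled_signal(values, dt = template$dt, t0 = template$t0)
}

#' Evaluate a sampled signal at arbitrary times
#'
#' Linear interpolation between samples; times before the first sample return
#' the first sample (hold-first) and times after the last return the last.
#'
#' @param x a `sampled_signal`.
#' @param t numeric vector of times (s).
#' @return numeric vector of interpolated values.
#' @keywords internal
signal_at <- function(x, t) {
  tt <- signal_time(x)
  stats::approx(tt, x$values, xout = t, rule = 2)$y
}

#' Delay a signal in time
#'
#' Returns `x(t - tau)`. On-grid delays (tau an integer number of samples)
#' are implemented as an exact sample shift; off-grid delays use linear
#' interpolation. The pre-history (times before `t0 + tau`) is filled by
#' holding the first sample, matching trials that start with hand and cursor
#' aligned.
#'
#' @param x a `sampled_signal`.
#' @param tau delay in seconds, `tau >= 0`.
#' @return a `sampled_signal` on the same grid.
#' @export
apply_delay <- function(x, tau) {
  stopifnot(inherits(x, "sampled_signal"))
  if (!is.finite(tau) || tau < 0) stop("tau must be >= 0")
  if (tau == 0) return(x)
  n <- length(x$values)
  k <- tau / x$dt
  if (abs(k - round(k)) < 1e-9) {
    k <- as.integer(round(k))
    if (k >= n) return(as_signal_like(rep(x$values[1L], n), x))
    out <- c(rep(x$values[1L], k), x$values[seq_len(n - k)])
  } else {
    out <- signal_at(x, signal_time(x) - tau)
  }
  as_signal_like(out, x)
}

#' Shift a signal in time (either direction)
#'
#' `shift > 0` delays the signal (`x(t - shift)`); `shift < 0` advances it.
#' Out-of-range samples are held at the nearest endpoint.
#'
#' @param x a `sampled_signal`.
#' @param shift time shift in seconds.
#' @return a `sampled_signal` on the same grid.
#' @export
shift_signal <- function(x, shift) {
  stopifnot(inherits(x, "sampled_signal"))
  if (shift == 0) return(x)
  if (shift > 0) return(apply_delay(x, shift))
  n <- length(x$values)
  k <- -shift / x$dt
  if (abs(k - round(k)) < 1e-9) {
    k <- as.integer(round(k))
    if (k >= n) return(as_signal_like(rep(x$values[n], n), x))
    out <- c(x$values[(k + 1L):n], rep(x$values[n], k))
  } else {
    out <- signal_at(x, signal_time(x) - shift)
  }
  as_signal_like(out, x)
}

#' Numerical time derivative (central differences)
#'
#' Second-order central differences in the interior, one-sided at the ends.
#'
#' @param x a `sampled_signal`.
#' @return a `sampled_signal` holding dx/dt.
#' @export
signal_deriv <- function(x) {
  stopifnot(inherits(x, "sampled_signal"))
  v <- x$values
  n <- length(v)
  if (n < 3L) stop("signal too short to differentiate")
  d <- numeric(n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * x$dt)
  d[1] <- (v[2] - v[1]) / x$dt
  d[n] <- (v[n] - v[n - 1]) / x$dt
  as_signal_like(d, x)
}

#' Second-order Taylor advance of a signal
#'
#' Approximates `x(t + tau)` by the truncated Taylor expansion
#' `x(t) + tau * x'(t) + tau^2/2 * x''(t)`, with derivatives taken by central
#' differences. Exact (up to the difference stencil) for polynomials of
#' degree <= 2; for sinusoids the error shrinks as `O((tau*omega)^3)`.
#'
#' @param x a `sampled_signal`.
#' @param tau look-ahead in seconds, `tau >= 0`.
#' @return a `sampled_signal` on the same grid.
#' @export
taylor_advance <- function(x, tau) {
  stopifnot(inherits(x, "sampled_signal"))
  if (!is.finite(tau) || tau < 0) stop("tau must be >= 0")
  if (length(x$values) < 5L) stop("signal too short for the Taylor stencil")
  if (tau == 0) return(x)
  v <- signal_deriv(x)
  a <- signal_deriv(v)
  as_signal_like(x$values + tau * v$values + tau^2 / 2 * a$values, x)
}
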