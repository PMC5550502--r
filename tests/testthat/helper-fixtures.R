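# shared fixtures: the experiment's operating point and small helpers
OMEGA0 <- 2 * pi * 0.556
TAU0 <- 0.25
AMP0 <- 0.06

sin_signal <- function(duration = 10, omega = OMEGA0, amp = 1, phase = 0,
                       dt = 1 / 400) {
  t <- seq(0, duration - dt, by = dt)
  sampled_signal(amp * sin(omega * t + phase), dt = dt, t0 = 0)
}

# steady-state amplitude and phase of a near-sinusoidal signal by projection
# onto sin/cos over a tail window
measure_phasor <- function(x, omega, from = NULL) {
  t <- signal_time(x)
  if (is.null(from)) from <- max(t) / 2
  idx <- t >= from
  X <- cbind(sin(omega * t[idx]), cos(omega * t[idx]))
  cf <- qr.solve(X, x$values[idx])
  list(amp = sqrt(sum(cf^2)), phase = atan2(cf[2], cf[1]))
}

# brute-force plateau RMSE straight from the definition
brute_rmse <- function(trial) {
  win <- plateau_window(trial$schedule)
  idx <- trial$t >= win[1] - 1e-9 & trial$t < win[2] - 1e-9
  sqrt(mean((trial$x_target[idx] - trial$x_cursor[idx])^2))
}

# brute-force lag search used as the independent oracle for xcorr_lag
brute_lag <- function(x, y, max_lag) {
  n <- length(x$values)
  L <- floor(max_lag / x$dt + 1e-9)
  lags <- -L:L
  cc <- vapply(lags, function(l) {
    if (l >= 0) stats::cor(x$values[seq_len(n - l)], y$values[(1 + l):n])
    else stats::cor(x$values[(1 - l):n], y$values[seq_len(n + l)])
  }, numeric(1))
  best <- max(cc)
  cand <- lags[cc >= best - 1e-12]
  cand[which.min(abs(cand))] * x$dt
}

default_fixed <- list(B_est = 27 * TAU0, M_est = 27 * TAU0^2 / 2)
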