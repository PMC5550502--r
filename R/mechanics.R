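#' Spring-mass-damper parameters of the hand-cursor link
#'
#' The Mechanical condition links hand and cursor through
#' `x_hand = x_cursor + (B/K) * dx_cursor + (M/K) * d2x_cursor`, so only the
#' two ratios `B/K` (s) and `M/K` (s^2) matter for the dynamics. Absolute
#' values of K, B and M may be attached for force computations.
#'
#' @param ratio_b damping ratio B/K in seconds (>= 0).
#' @param ratio_m mass ratio M/K in seconds^2 (>= 0).
#' @param K,B,M optional absolute spring (N/m), damper (N s/m) and mass (kg);
#'   when all are given they must be consistent with the ratios.
#' @return an object of class `mechanical_params`.
#' @export
mechanical_params <- function(ratio_b, ratio_m, K = NULL, B = NULL, M = NULL) {
  if (!is.finite(ratio_b) || ratio_b < 0) stop("ratio_b must be >= 0")
  if (!is.finite(ratio_m) || ratio_m < 0) stop("ratio_m must be >= 0")
  if (!is.null(K)) {
    if (K <= 0) stop("K must be > 0")
    if (!is.null(B) && abs(B / K - ratio_b) > 1e-8) {
      stop("B/K inconsistent with ratio_b")
    }
    if (!is.null(M) && abs(M / K - ratio_m) > 1e-8) {
      stop("M/K inconsistent with ratio_m")
    }
  }
  structure(list(ratio_b = ratio_b, ratio_m = ratio_m, K = K, B = B, M = M),
            class = "mechanical_params")
}

#' @export
print.mechanical_params <- function(x, ...) {
  cat(sprintf("<mechanical_params> B/K = %.5g s, M/K = %.5g s^2%s\n",
              x$ratio_b, x$ratio_m,
              if (!is.null(x$K)) sprintf(", K = %.4g N/m", x$K) else ""))
  invisible(x)
}

#' Mechanical equivalent of a time delay
#'
#' The second-order Taylor truncation of the delay operator corresponds to a
#' spring-mass-damper system with `B/K = tau` and `M/K = tau^2/2`. Any such
#' system is underdamped with damping ratio `1/sqrt(2)` independent of tau.
#'
#' @param tau delay in seconds (>= 0).
#' @param K optional absolute spring constant (N/m); when given, B and M are
#'   derived as `K*tau` and `K*tau^2/2`.
#' @return a `mechanical_params` object.
#' @export
mechanical_from_delay <- function(tau, K = NULL) {
  if (!is.finite(tau) || tau < 0) stop("tau must be >= 0")
  mechanical_params(ratio_b = tau, ratio_m = tau^2 / 2, K = K,
                    B = if (!is.null(K)) K * tau else NULL,
                    M = if (!is.null(K)) K * tau^2 / 2 else NULL)
}

#' Frequency response of the delay operator (hand over cursor)
#'
#' `X_hand(s)/X_cursor(s) = exp(tau*s)`: unit gain at every frequency and a
#' phase advance of `tau*omega` radians, i.e. a constant temporal lead of
#' `tau` seconds of the hand over the cursor.
#'
#' @param tau delay in seconds.
#' @param omega angular frequency in rad/s (> 0), vectorised.
#' @return list with components `gain`, `phase_rad`, `phase_sec`.
#' @export
delay_transfer <- function(tau, omega) {
  if (any(!is.finite(omega)) || any(omega <= 0)) stop("omega must be > 0")
  if (!is.finite(tau) || tau < 0) stop("tau must be >= 0")
  list(gain = rep(1, length(omega)),
       phase_rad = tau * omega,
       phase_sec = rep(tau, length(omega)))
}

#' Frequency response of a spring-mass-damper link (hand over cursor)
#'
#' For ratios `(rb, rm)` the transfer function is
#' `H(j*omega) = 1 - rm*omega^2 + j*rb*omega`. The phase uses the
#' two-argument arctangent so it grows continuously past pi/2 when the real
#' part turns negative (`tau*omega >= sqrt(2)` for the delay-derived system).
#'
#' @param ratio_b B/K in seconds.
#' @param ratio_m M/K in seconds^2.
#' @param omega angular frequency in rad/s (> 0), vectorised.
#' @return list with components `gain`, `phase_rad`, `phase_sec`.
#' @export
mech_ratio_transfer <- function(ratio_b, ratio_m, omega) {
  if (any(!is.finite(omega)) || any(omega <= 0)) stop("omega must be > 0")
  re <- 1 - ratio_m * omega^2
  im <- ratio_b * omega
  ph <- atan2(im, re)
  list(gain = sqrt(re^2 + im^2), phase_rad = ph, phase_sec = ph / omega)
}

#' Frequency response of the mechanical approximation to a delay
#'
#' Convenience wrapper for [mech_ratio_transfer()] with the delay-derived
#' ratios `B/K = tau`, `M/K = tau^2/2`. At the experiment's operating point
#' (tau = 0.25 s, omega = 2*pi*0.556 rad/s) the temporal shift is 0.27 s and
#' the gain is `sqrt(1 + tau^4*omega^4/4)` (about 1.070).
#'
#' @inheritParams delay_transfer
#' @return list with components `gain`, `phase_rad`, `phase_sec`.
#' @export
mechanical_transfer <- function(tau, omega) {
  if (!is.finite(tau) || tau < 0) stop("tau must be >= 0")
  mech_ratio_transfer(tau, tau^2 / 2, omega)
}

#' Frequency responses of both operators on a grid
#'
#' @param tau delay in seconds.
#' @param omega_grid strictly positive, increasing angular frequencies (rad/s).
#' @return list with two data.frames, `delay` and `mechanical`, each with
#'   columns `omega_rad_s`, `gain`, `phase_rad`, `phase_sec`.
#' @export
bode_data <- function(tau, omega_grid) {
  if (any(!is.finite(omega_grid)) || any(omega_grid <= 0)) {
    stop("omega_grid must be strictly positive")
  }
  if (is.unsorted(omega_grid, strictly = TRUE)) {
    stop("omega_grid must be strictly increasing")
  }
  d <- delay_transfer(tau, omega_grid)
  m <- mechanical_transfer(tau, omega_grid)
  list(
    delay = data.frame(omega_rad_s = omega_grid, gain = d$gain,
                       phase_rad = d$phase_rad, phase_sec = d$phase_sec),
    mechanical = data.frame(omega_rad_s = omega_grid, gain = m$gain,
                            phase_rad = m$phase_rad, phase_sec = m$phase_sec)
  )
}

# RK4 step matrices are not precomputed: the inner loop is scalar arithmetic
# on the 2-state system, cheap enough at 400 Hz trial lengths.
rk4_mech <- function(xh, dt, b, m, x0, v0, snap_m) {
  n <- length(xh)
  x <- numeric(n)
  v <- numeric(n)
  x[1] <- x0
  v[1] <- v0
  # forcing at half-steps by linear interpolation
  xh_mid <- c((xh[-n] + xh[-1]) / 2, xh[n])
  b0 <- b; bm <- c((b[-n] + b[-1]) / 2, b[n])
  m0 <- m; mm <- c((m[-n] + m[-1]) / 2, m[n])
  for (i in seq_len(n - 1L)) {
    if (m0[i + 1L] < snap_m) {
      # stiffness limit: the link is rigid on this time scale
      x[i + 1L] <- xh[i + 1L]
      v[i + 1L] <- (xh[i + 1L] - xh[i]) / dt
      next
    }
    xi <- x[i]; vi <- v[i]
    f1 <- xh[i];        b1 <- b0[i];        m1 <- m0[i]
    f2 <- xh_mid[i];    b2 <- bm[i];        m2 <- mm[i]
    f4 <- xh[i + 1L];   b4 <- b0[i + 1L];   m4 <- m0[i + 1L]
    k1x <- vi
    k1v <- (f1 - xi - b1 * vi) / m1
    x2 <- xi + dt / 2 * k1x; v2 <- vi + dt / 2 * k1v
    k2x <- v2
    k2v <- (f2 - x2 - b2 * v2) / m2
    x3 <- xi + dt / 2 * k2x; v3 <- vi + dt / 2 * k2v
    k3x <- v3
    k3v <- (f2 - x3 - b2 * v3) / m2
    x4 <- xi + dt * k3x; v4 <- vi + dt * k3v
    k4x <- v4
    k4v <- (f4 - x4 - b4 * v4) / m4
    x[i + 1L] <- xi + dt / 6 * (k1x + 2 * k2x + 2 * k3x + k4x)
    v[i + 1L] <- vi + dt / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
  }
  list(x = x, v = v)
}

rk4_first_order <- function(xh, dt, b, x0) {
  n <- length(xh)
  x <- numeric(n)
  x[1] <- x0
  xh_mid <- c((xh[-n] + xh[-1]) / 2, xh[n])
  for (i in seq_len(n - 1L)) {
    xi <- x[i]
    k1 <- (xh[i] - xi) / b
    k2 <- (xh_mid[i] - (xi + dt / 2 * k1)) / b
    k3 <- (xh_mid[i] - (xi + dt / 2 * k2)) / b
    k4 <- (xh[i + 1L] - (xi + dt * k3)) / b
    x[i + 1L] <- xi + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  x
}

#' Forward simulation of the mechanical cursor
#'
#' Integrates `(M/K) x_c'' + (B/K) x_c' + x_c = x_hand(t)` with a fixed-step
#' 4th-order Runge-Kutta scheme at the signal's sampling rate, interpolating
#' the forcing linearly between samples. When the ratios derive from a delay
#' tau, the system is underdamped with damping ratio `1/sqrt(2)`.
#'
#' @param x_hand hand position, a `sampled_signal`.
#' @param params a `mechanical_params` object.
#' @param init_pos initial cursor position (m); defaults to the first hand
#'   sample (trials start aligned).
#' @param init_vel initial cursor velocity (m/s), default 0.
#' @return cursor position as a `sampled_signal`.
#' @export
simulate_mechanical_cursor <- function(x_hand, params, init_pos = NULL,
                                       init_vel = 0) {
  stopifnot(inherits(x_hand, "sampled_signal"),
            inherits(params, "mechanical_params"))
  xh <- x_hand$values
  n <- length(xh)
  if (is.null(init_pos)) init_pos <- xh[1L]
  rb <- params$ratio_b
  rm_ <- params$ratio_m
  if (rm_ == 0 && rb == 0) return(x_hand)
  if (rm_ == 0) {
    return(as_signal_like(rk4_first_order(xh, x_hand$dt, rb, init_pos), x_hand))
  }
  out <- rk4_mech(xh, x_hand$dt, rep(rb, n), rep(rm_, n),
                  init_pos, init_vel, snap_m = 0)
  as_signal_like(out$x, x_hand)
}

#' Cursor produced by a trial condition with the within-trial ramp
#'
#' Applies the condition operator to a hand signal, following the trial's
#' ramp-plateau-ramp profile: `"N"` returns the hand unchanged, `"D"` delays
#' the hand by the time-varying `tau(t)` of the schedule, and `"M"` integrates
#' the spring-mass-damper link with time-varying ratios
#' `(B/K, M/K) = (tau(t), tau(t)^2/2)`.
#'
#' For `"M"`, near the aligned segments `tau(t) -> 0` makes the link stiffer
#' than the integrator can resolve; below `tau_snap` the cursor is clamped to
#' the hand (the rigid limit of the link).
#'
#' @param x_hand hand position, a `sampled_signal` starting at the trial start.
#' @param condition one of `"N"`, `"D"`, `"M"`.
#' @param schedule a `delay_schedule`.
#' @param tau_snap rigid-limit threshold for the mechanical ramp (s).
#' @return cursor position as a `sampled_signal`.
#' @export
condition_cursor <- function(x_hand, condition, schedule,
                             tau_snap = 0.005) {
  stopifnot(inherits(x_hand, "sampled_signal"))
  condition <- match.arg(condition, c("N", "D", "M"))
  if (condition == "N") return(x_hand)
  t <- signal_time(x_hand)
  tau_t <- delay_at_time(pmin(t, trial_duration(schedule)), schedule)
  if (condition == "D") {
    return(as_signal_like(signal_at(x_hand, t - tau_t), x_hand))
  }
  out <- rk4_mech(x_hand$values, x_hand$dt, b = tau_t, m = tau_t^2 / 2,
                  x0 = x_hand$values[1L],
                  v0 = 0,
                  snap_m = tau_snap^2 / 2)
  as_signal_like(out$x, x_hand)
}

#' Export frequency-response tables
#'
#' Writes the delay-operator and mechanical-operator frequency responses as
#' plain-text columnar files with header
#' `omega_rad_s gain phase_rad phase_sec`.
#'
#' @param bode result of [bode_data()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_freq_response <- function(bode, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(bode)) {
    p <- file.path(dir, paste0("freq_response_", nm, ".tsv"))
    utils::write.table(bode[[nm]], p, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
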