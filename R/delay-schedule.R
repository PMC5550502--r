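#' Target motion parameters
#'
#' The target moves sinusoidally, `x_target(t) = A * sin(omega * t)`.
#' Defaults are the experiment's values: amplitude 6 cm, frequency 0.556 Hz.
#'
#' @param amplitude amplitude in metres (> 0).
#' @param omega angular frequency in rad/s (> 0).
#' @return an object of class `target_motion`.
#' @export
target_motion <- function(amplitude = 0.06, omega = 2 * pi * 0.556) {
  if (!is.finite(amplitude) || amplitude <= 0) stop("amplitude must be > 0")
  if (!is.finite(omega) || omega <= 0) stop("omega must be > 0")
  structure(list(amplitude = amplitude, omega = omega),
            class = "target_motion")
}

#' @export
print.target_motion <- function(x, ...) {
  cat(sprintf("<target_motion> A = %.4g m, f = %.4g Hz\n",
              x$amplitude, x$omega / (2 * pi)))
  invisible(x)
}

#' Target position on a time grid
#' @param motion a `target_motion`.
#' @param t numeric vector of times (s).
#' @return numeric vector, metres.
#' @export
target_position <- function(motion, t) {
  motion$amplitude * sin(motion$omega * t)
}

#' Within-trial manipulation schedule
#'
#' Piecewise-linear profile of the manipulation parameter within one trial:
#' an aligned head, a linear ramp up to the plateau value, a plateau, a ramp
#' down, and an aligned tail. Defaults are the experiment's 5/10/80/10/5 s
#' profile with a 0.25 s plateau delay.
#'
#' @param aligned_head,ramp_up,plateau,ramp_down,aligned_tail durations (s).
#' @param plateau_value plateau delay value tau (s).
#' @return an object of class `delay_schedule`.
#' @export
delay_schedule <- function(aligned_head = 5, ramp_up = 10, plateau = 80,
                           ramp_down = 10, aligned_tail = 5,
                           plateau_value = 0.25) {
  durs <- c(aligned_head, ramp_up, plateau, ramp_down, aligned_tail)
  if (any(!is.finite(durs)) || any(durs < 0)) {
    stop("all schedule durations must be finite and >= 0")
  }
  if (!is.finite(plateau_value) || plateau_value < 0) {
    stop("plateau_value must be >= 0")
  }
  structure(list(aligned_head = aligned_head, ramp_up = ramp_up,
                 plateau = plateau, ramp_down = ramp_down,
                 aligned_tail = aligned_tail, plateau_value = plateau_value),
            class = "delay_schedule")
}

#' @export
print.delay_schedule <- function(x, ...) {
  cat(sprintf(
    "<delay_schedule> %g + %g + %g + %g + %g s, plateau tau = %g s\n",
    x$aligned_head, x$ramp_up, x$plateau, x$ramp_down, x$aligned_tail,
    x$plateau_value))
  invisible(x)
}

#' Total trial duration of a schedule
#' @param schedule a `delay_schedule`.
#' @return duration in seconds.
#' @export
trial_duration <- function(schedule) {
  schedule$aligned_head + schedule$ramp_up + schedule$plateau +
    schedule$ramp_down + schedule$aligned_tail
}

#' Plateau time window of a schedule
#' @param schedule a `delay_schedule`.
#' @return numeric length-2 vector `c(start, end)` in seconds.
#' @export
plateau_window <- function(schedule) {
  start <- schedule$aligned_head + schedule$ramp_up
  c(start, start + schedule$plateau)
}

#' Manipulation value at a time within the trial
#'
#' Continuous piecewise-linear evaluation of the schedule: 0 on the aligned
#' head and tail, linear on the ramps, `plateau_value` on the plateau.
#'
#' @param t numeric vector of times (s), each within `[0, trial_duration]`.
#' @param schedule a `delay_schedule`.
#' @return numeric vector of delay values (s).
#' @export
delay_at_time <- function(t, schedule) {
  dur <- trial_duration(schedule)
  if (any(!is.finite(t)) || any(t < -1e-9) || any(t > dur + 1e-9)) {
    stop("t must lie within [0, trial duration]")
  }
  s <- schedule
  t1 <- s$aligned_head
  t2 <- t1 + s$ramp_up
  t3 <- t2 + s$plateau
  t4 <- t3 + s$ramp_down
  v <- numeric(length(t))
  up <- t > t1 & t < t2
  if (s$ramp_up > 0) v[up] <- s$plateau_value * (t[up] - t1) / s$ramp_up
  v[t >= t2 & t <= t3] <- s$plateau_value
  dn <- t > t3 & t < t4
  if (s$ramp_down > 0) v[dn] <- s$plateau_value * (t4 - t[dn]) / s$ramp_down
  v
}
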