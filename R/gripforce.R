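#' Inertial load force from a position signal
#'
#' The load force on the hand during rhythmic motion with a held handle is
#' the handle mass times its acceleration. Acceleration is obtained by
#' double central differencing of position, then zero-phase low-pass
#' filtered (Butterworth, applied forward and backward so the net phase
#' shift is zero).
#'
#' @param x_hand hand/handle position, a `sampled_signal`.
#' @param mass handle mass in kg (> 0). The phase metrics downstream are
#'   mass-invariant (mass scales the load uniformly); only force ratios in
#'   physical units depend on it.
#' @param cutoff low-pass cutoff in Hz (default 12), below Nyquist.
#' @param order Butterworth order (default 4) of each pass.
#' @return load force as a `sampled_signal` (N).
#' @export
load_force <- function(x_hand, mass = 0.1, cutoff = 12, order = 4) {
  stopifnot(inherits(x_hand, "sampled_signal"))
  if (!is.finite(mass) || mass <= 0) stop("mass must be > 0")
  fs <- 1 / x_hand$dt
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  acc <- signal_deriv(signal_deriv(x_hand))$values
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  acc_f <- signal::filtfilt(bf, acc)
  as_signal_like(mass * acc_f, x_hand)
}

#' Virtual spring force between hand and cursor
#'
#' `F(t) = K * (x_hand(t) - x_cursor(t))`: the force the spring of the
#' mechanical hand-cursor model would exert given the instantaneous stretch.
#' Adding it to the measured inertial load tests whether grip force was
#' programmed for the total (real plus illusory) load.
#'
#' @param x_hand,x_cursor aligned `sampled_signal`s (m).
#' @param K spring constant in N/m (> 0).
#' @return virtual force as a `sampled_signal` (N).
#' @export
virtual_spring_force <- function(x_hand, x_cursor, K) {
  stopifnot(inherits(x_hand, "sampled_signal"),
            inherits(x_cursor, "sampled_signal"))
  if (!is.finite(K) || K <= 0) stop("K must be > 0")
  if (length(x_hand$values) != length(x_cursor$values)) {
    stop("hand and cursor signals must be aligned")
  }
  as_signal_like(K * (x_hand$values - x_cursor$values), x_hand)
}

gf_segment_window <- function(segments, segment_length = 5) {
  # 1-based inclusive segment indices -> window bounds in seconds
  c(min(segments) - 1, max(segments)) * segment_length
}

#' Grip-force/load-force temporal phase
#'
#' Cross-correlation lag between grip force and the rectified load force,
#' computed per 5-s segment and averaged over the segments where the
#' manipulation is at its maximum (segments 4-19 of a 110-s trial).
#' Positive phase means grip force leads load force.
#'
#' The rectified load has half the movement period (~0.9 s), so the search
#' window defaults to 0.4 s, below a quarter movement period, to avoid
#' rectification aliasing.
#'
#' @param gf grip force, a `sampled_signal` (N).
#' @param lf load force, a `sampled_signal` (N); rectified internally.
#' @param segments 1-based segment indices to average (default 4:19).
#' @param segment_length segment length (s), default 5.
#' @param max_lag cross-correlation half-window (s), default 0.4.
#' @return mean phase in seconds.
#' @export
gf_lf_phase <- function(gf, lf, segments = 4:19, segment_length = 5,
                        max_lag = 0.4) {
  stopifnot(inherits(gf, "sampled_signal"), inherits(lf, "sampled_signal"))
  lf_rect <- as_signal_like(abs(lf$values), lf)
  segs_g <- segment_signal(gf, segment_length)
  segs_l <- segment_signal(lf_rect, segment_length)
  if (max(segments) > length(segs_g)) stop("segment index out of range")
  lags <- mapply(function(a, b) xcorr_lag(a, b, max_lag),
                 segs_g[segments], segs_l[segments])
  mean(lags)
}

#' Grip-force to load-force ratio
#'
#' Mean grip force over mean rectified load force, over the maximum-
#' manipulation segments (4-19 by default). The load oscillates about zero,
#' so its mean is taken on the rectified signal.
#'
#' @inheritParams gf_lf_phase
#' @return dimensionless ratio.
#' @export
gf_lf_ratio <- function(gf, lf, segments = 4:19, segment_length = 5) {
  stopifnot(inherits(gf, "sampled_signal"), inherits(lf, "sampled_signal"))
  win <- gf_segment_window(segments, segment_length)
  tg <- signal_time(gf)
  idx <- tg >= gf$t0 + win[1] - 1e-9 & tg < gf$t0 + win[2] - 1e-9
  if (!any(idx)) stop("segments outside the signal")
  denom <- mean(abs(lf$values[idx]))
  if (denom == 0) stop("load force is identically zero on the window")
  mean(gf$values[idx]) / denom
}

#' Grip metrics of one trial
#'
#' Assembles the grip-force analysis of a trial: inertial load force from the
#' hand position, raw GF-LF phase and ratio, and both metrics after
#' correcting the load with the virtual spring force `K * (hand - cursor)`.
#'
#' @param trial a `trial_record` carrying grip force.
#' @param mass handle mass (kg).
#' @param K virtual spring constant (N/m, > 0).
#' @param segments segments to average (default 4:19).
#' @param max_lag phase search half-window (s).
#' @return an object of class `grip_metrics`: list with `phase_s`, `ratio`,
#'   `corrected_phase_s`, `corrected_ratio`, `K_used`, `mass_used`.
#' @export
grip_metrics <- function(trial, mass = 0.1, K = 27, segments = 4:19,
                         max_lag = 0.4) {
  stopifnot(inherits(trial, "trial_record"))
  if (is.null(trial$grip_force)) stop("trial has no grip-force series")
  if (!is.finite(K) || K <= 0) stop("K must be > 0")
  gf <- trial_signal(trial, "grip_force")
  hand <- trial_signal(trial, "x_hand")
  cursor <- trial_signal(trial, "x_cursor")
  lf <- load_force(hand, mass = mass)
  fv <- virtual_spring_force(hand, cursor, K)
  lf_corr <- as_signal_like(lf$values + fv$values, lf)
  structure(list(
    phase_s = gf_lf_phase(gf, lf, segments, max_lag = max_lag),
    ratio = gf_lf_ratio(gf, lf, segments),
    corrected_phase_s = gf_lf_phase(gf, lf_corr, segments, max_lag = max_lag),
    corrected_ratio = gf_lf_ratio(gf, lf_corr, segments),
    K_used = K, mass_used = mass),
    class = "grip_metrics")
}

#' @export
print.grip_metrics <- function(x, ...) {
  cat(sprintf(
    "<grip_metrics> phase %.4g s (corrected %.4g s), GF/LF %.4g (corrected %.4g), K = %g N/m\n",
    x$phase_s, x$corrected_phase_s, x$ratio, x$corrected_ratio, x$K_used))
  invisible(x)
}
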