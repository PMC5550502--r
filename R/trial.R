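#' One tracking trial
#'
#' Aligned time series of target, hand and cursor positions (m) and,
#' optionally, grip force (N), with the condition label and the within-trial
#' manipulation schedule.
#'
#' @param t sample times (s), uniform, starting at the trial start.
#' @param x_target,x_hand,x_cursor position series (m), equal lengths.
#' @param grip_force optional grip-force series (N).
#' @param condition `"N"`, `"D"` or `"M"`.
#' @param schedule the trial's `delay_schedule`.
#' @return an object of class `trial_record`.
#' @export
trial_record <- function(t, x_target, x_hand, x_cursor, grip_force = NULL,
                         condition = c("N", "D", "M"),
                         schedule = delay_schedule()) {
  condition <- match.arg(condition)
  n <- length(t)
  if (n < 2L) stop("a trial needs at least 2 samples")
  lens <- c(length(x_target), length(x_hand), length(x_cursor))
  if (any(lens != n)) stop("all trial series must have equal length")
  if (!is.null(grip_force) && length(grip_force) != n) {
    stop("grip_force length must match the other series")
  }
  dts <- diff(t)
  dt <- dts[1]
  if (any(abs(dts - dt) > 1e-6 * dt)) stop("trial time base is not uniform")
  structure(list(t = as.numeric(t), x_target = as.numeric(x_target),
                 x_hand = as.numeric(x_hand), x_cursor = as.numeric(x_cursor),
                 grip_force = if (is.null(grip_force)) NULL
                              else as.numeric(grip_force),
                 condition = condition, sampling_rate = 1 / dt,
                 schedule = schedule),
            class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf(
    "<trial_record> condition %s, %.4g s at %.6g Hz (%d samples)%s\n",
    x$condition, x$t[length(x$t)] - x$t[1] + 1 / x$sampling_rate,
    x$sampling_rate, length(x$t),
    if (is.null(x$grip_force)) "" else ", with grip force"))
  invisible(x)
}

#' Extract a trial series as a sampled_signal
#' @param trial a `trial_record`.
#' @param what one of `"x_target"`, `"x_hand"`, `"x_cursor"`, `"grip_force"`.
#' @return a `sampled_signal`.
#' @export
trial_signal <- function(trial, what = c("x_target", "x_hand", "x_cursor",
                                         "grip_force")) {
  stopifnot(inherits(trial, "trial_record"))
  what <- match.arg(what)
  v <- trial[[what]]
  if (is.null(v)) stop(sprintf("trial has no %s series", what))
  sampled_signal(v, dt = 1 / trial$sampling_rate, t0 = trial$t[1])
}

trial_time_grid <- function(schedule, dt = 1 / 400) {
  dur <- trial_duration(schedule)
  n <- round(dur / dt)
  dt * (seq_len(n) - 1L)
}

#' Exact sampled RMSE between two sinusoids
#'
#' Root-mean-square of `a1*sin(omega*t + phi1) - a2*sin(omega*t + phi2)` over
#' the uniform grid `t = t0 + dt*(0:(n-1))`, evaluated in closed form via the
#' geometric sum of the second-harmonic term, so it matches the sample-by-
#' sample computation to machine precision at any window length.
#'
#' @param a1,phi1,a2,phi2 amplitudes (m) and phases (rad) of the sinusoids.
#' @param omega angular frequency (rad/s).
#' @param t0 first sample time (s); `dt` sampling step (s); `n` sample count.
#' @return RMSE in metres.
#' @export
sampled_sinusoid_rmse <- function(a1, phi1, a2, phi2, omega, t0, dt, n) {
  delta <- a1 * exp(1i * phi1) - a2 * exp(1i * phi2)
  amp <- Mod(delta)
  if (amp == 0) return(0)
  psi <- Arg(delta)
  # mean(sin^2(omega*t + psi)) over the grid
  z <- exp(2i * omega * dt)
  G <- if (Mod(z - 1) < 1e-12) n + 0i else (1 - z^n) / (1 - z)
  m2 <- 0.5 - Re(exp(2i * (omega * t0 + psi)) * G) / (2 * n)
  amp * sqrt(max(m2, 0))
}

# exact steady-state complex gain (cursor per unit hand phasor) of the
# fixed-step RK4 recursion with linearly interpolated forcing: the step is
# linear in (x, v, f_n, f_mid, f_{n+1}), so its matrices are probed with
# basis inputs and the discrete transfer solved at z = exp(i*omega*dt)
discrete_mech_gain <- function(ratio_b, ratio_m, omega, dt) {
  if (ratio_m == 0 && ratio_b == 0) return(1 + 0i)
  step <- function(x, v, f1, f2, f4) {
    if (ratio_m == 0) {
      k1 <- (f1 - x) / ratio_b
      k2 <- (f2 - (x + dt / 2 * k1)) / ratio_b
      k3 <- (f2 - (x + dt / 2 * k2)) / ratio_b
      k4 <- (f4 - (x + dt * k3)) / ratio_b
      return(c(x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0))
    }
    k1x <- v;                      k1v <- (f1 - x - ratio_b * v) / ratio_m
    x2 <- x + dt / 2 * k1x;        v2 <- v + dt / 2 * k1v
    k2x <- v2;                     k2v <- (f2 - x2 - ratio_b * v2) / ratio_m
    x3 <- x + dt / 2 * k2x;        v3 <- v + dt / 2 * k2v
    k3x <- v3;                     k3v <- (f2 - x3 - ratio_b * v3) / ratio_m
    x4 <- x + dt * k3x;            v4 <- v + dt * k3v
    k4x <- v4;                     k4v <- (f4 - x4 - ratio_b * v4) / ratio_m
    c(x + dt / 6 * (k1x + 2 * k2x + 2 * k3x + k4x),
      v + dt / 6 * (k1v + 2 * k2v + 2 * k3v + k4v))
  }
  M <- cbind(step(1, 0, 0, 0, 0), step(0, 1, 0, 0, 0))
  C1 <- step(0, 0, 1, 0, 0); C2 <- step(0, 0, 0, 1, 0)
  C4 <- step(0, 0, 0, 0, 1)
  z <- exp(1i * omega * dt)
  rhs <- C1 + C2 * (1 + z) / 2 + C4 * z
  G <- solve(diag(2) * z - M, rhs)
  G[1]
}

#' Closed-form plateau RMSE of a simulated trial
#'
#' Steady-state prediction of the plateau tracking error for a hand command
#' generated by a representation and a cursor produced by a condition
#' operator. The hand is a sinusoid (gain/phase from the representation);
#' the cursor is its image under the condition's steady-state response — for
#' the Mechanical condition the exact steady state of the discrete RK4
#' integrator, so the prediction matches [run_trial()] to the integrator's
#' transient accuracy (~1e-8 m) rather than only to the continuous transfer
#' function. The RMSE against the target is evaluated in closed form on the
#' exact plateau sample grid.
#'
#' @param state a `representation_state`.
#' @param condition `"N"`, `"D"` or `"M"`.
#' @param motion a `target_motion`.
#' @param schedule a `delay_schedule`.
#' @param dt sampling step (s).
#' @return predicted plateau RMSE (m).
#' @export
predict_plateau_rmse <- function(state, condition, motion, schedule,
                                 dt = 1 / 400) {
  condition <- match.arg(condition, c("N", "D", "M"))
  w <- motion$omega
  tr <- representation_transfer(state, w)
  a_h <- motion$amplitude * tr$gain
  ph_h <- tr$phase_rad
  tau <- schedule$plateau_value
  if (condition == "N") {
    a_c <- a_h; ph_c <- ph_h
  } else if (condition == "D") {
    a_c <- a_h; ph_c <- ph_h - w * tau
  } else {
    G <- discrete_mech_gain(tau, tau^2 / 2, w, dt)
    a_c <- a_h * Mod(G); ph_c <- ph_h + Arg(G)
  }
  win <- plateau_window(schedule)
  n <- round((win[2] - win[1]) / dt)
  sampled_sinusoid_rmse(a_c, ph_c, motion$amplitude, 0, w,
                        t0 = win[1], dt = dt, n = n)
}

#' Simulate one trial of the feed-forward internal-model simulator
#'
#' The hand command comes from the representation (delayed-state or
#' mechanical); the cursor is produced by the actual condition operator with
#' the within-trial ramp; the plateau RMSE between target and cursor is the
#' trial's tracking error.
#'
#' @param state a `representation_state`.
#' @param condition `"N"`, `"D"` or `"M"`.
#' @param motion a `target_motion`.
#' @param schedule a `delay_schedule`.
#' @param dt sampling step (s), default 1/400.
#' @return list with `trial` (a `trial_record`) and `rmse` (m).
#' @export
run_trial <- function(state, condition, motion = target_motion(),
                      schedule = delay_schedule(), dt = 1 / 400) {
  condition <- match.arg(condition, c("N", "D", "M"))
  t_grid <- trial_time_grid(schedule, dt)
  hand <- if (state$kind == "delayed_state") {
    hand_delayed_state(state, motion, t_grid)
  } else {
    hand_mechanical_rep(state, motion, t_grid)
  }
  cursor <- condition_cursor(hand, condition, schedule)
  trial <- trial_record(t_grid, target_position(motion, t_grid),
                        hand$values, cursor$values,
                        condition = condition, schedule = schedule)
  list(trial = trial, rmse = plateau_rmse(trial))
}

normal_state <- function(rep_kind) {
  if (rep_kind == "delayed_state") {
    representation_state("delayed_state", tau_est = 0)
  } else {
    representation_state("mechanical", K_est = 100, B_est = 0, M_est = 0)
  }
}

state_for_trial <- function(rep_kind, value, fixed_params) {
  if (rep_kind == "delayed_state") {
    representation_state("delayed_state", tau_est = value)
  } else {
    representation_state("mechanical", K_est = value,
                         B_est = fixed_params$B_est,
                         M_est = fixed_params$M_est)
  }
}

#' Simulate a full group protocol
#'
#' Runs the 19-trial protocol with the representation's parameter following
#' the adaptation schedule over the 16 manipulation trials (familiarization
#' trials use a zeroed representation). For the mechanical representation the
#' estimated spring `K_est` carries the trial dependence while `B_est` and
#' `M_est` stay at their fixed constants.
#'
#' @param protocol a `protocol_spec`.
#' @param rep_kind `"delayed_state"` or `"mechanical"`.
#' @param schedule an `adaptation_schedule` for `tau_est` or `K_est`.
#' @param fixed_params for the mechanical kind, `list(B_est=, M_est=)`.
#' @param motion a `target_motion`; `delay_sched` the within-trial schedule.
#' @param dt sampling step (s).
#' @param method `"simulate"` runs the full per-trial simulation;
#'   `"closed_form"` uses [predict_plateau_rmse()] (no trial records kept).
#' @param keep_trials keep the per-trial `trial_record`s (simulate only).
#' @return an object of class `simulated_experiment`: list with `summary`
#'   (data.frame: trial, condition, manip_index, param_value, rmse),
#'   `rep_kind`, `schedule`, and optionally `trials`.
#' @export
run_protocol <- function(protocol, rep_kind = c("delayed_state", "mechanical"),
                         schedule, fixed_params = NULL,
                         motion = target_motion(),
                         delay_sched = delay_schedule(), dt = 1 / 400,
                         method = c("simulate", "closed_form"),
                         keep_trials = FALSE) {
  rep_kind <- match.arg(rep_kind)
  method <- match.arg(method)
  stopifnot(inherits(protocol, "protocol_spec"),
            inherits(schedule, "adaptation_schedule"))
  if (rep_kind == "mechanical" &&
      (is.null(fixed_params$B_est) || is.null(fixed_params$M_est))) {
    stop("mechanical representation needs fixed_params$B_est and $M_est")
  }
  n_tr <- length(protocol$conditions)
  rmse <- numeric(n_tr)
  value <- numeric(n_tr)
  trials <- if (keep_trials) vector("list", n_tr) else NULL
  for (k in seq_len(n_tr)) {
    cond <- protocol$conditions[k]
    mi <- protocol$manip_index[k]
    st <- if (is.na(mi)) normal_state(rep_kind)
          else state_for_trial(rep_kind, schedule_value(schedule, mi),
                               fixed_params)
    value[k] <- if (is.na(mi)) NA_real_ else schedule_value(schedule, mi)
    if (method == "simulate") {
      res <- run_trial(st, cond, motion, delay_sched, dt)
      rmse[k] <- res$rmse
      if (keep_trials) trials[[k]] <- res$trial
    } else {
      rmse[k] <- predict_plateau_rmse(st, cond, motion, delay_sched, dt)
    }
  }
  structure(list(
    summary = data.frame(trial = seq_len(n_tr),
                         condition = protocol$conditions,
                         manip_index = protocol$manip_index,
                         param_value = value, rmse = rmse),
    rep_kind = rep_kind, schedule = schedule, fixed_params = fixed_params,
    protocol = protocol, trials = trials),
    class = "simulated_experiment")
}

#' @export
print.simulated_experiment <- function(x, ...) {
  cat(sprintf("<simulated_experiment> %s representation, %d trials\n",
              x$rep_kind, nrow(x$summary)))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Catch-trial RMSE contrast of a simulated experiment
#'
#' Mean, over the protocol's catch trials, of the catch-trial RMSE minus the
#' mean RMSE of the adjacent dominant-condition trials. A positive value
#' means catch trials are worse than their neighbours.
#'
#' @param experiment a `simulated_experiment` (or its `summary` data.frame
#'   plus a `protocol_spec`).
#' @param protocol the protocol; defaults to the experiment's own.
#' @return list with `mean_diff` (m) and per-catch `diffs`.
#' @export
catch_trial_contrast <- function(experiment, protocol = NULL) {
  if (inherits(experiment, "simulated_experiment")) {
    if (is.null(protocol)) protocol <- experiment$protocol
    s <- experiment$summary
  } else {
    s <- experiment
    if (is.null(protocol)) stop("need a protocol_spec")
  }
  dom <- dominant_trials(protocol)
  diffs <- vapply(protocol$catch_trials, function(k) {
    lower <- dom[dom < k]
    upper <- dom[dom > k]
    nb <- c(if (length(lower)) max(lower), if (length(upper)) min(upper))
    s$rmse[k] - mean(s$rmse[nb])
  }, numeric(1))
  list(mean_diff = mean(diffs), diffs = diffs)
}
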