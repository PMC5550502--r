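#' Internal representation of the hand-cursor dynamics
#'
#' Two competing feed-forward representations are modelled. The
#' *delayed-state* representation carries an explicit delay estimate
#' `tau_est` and phase-advances the motor command. The *mechanical*
#' representation carries estimates of the spring, damper and mass of a
#' virtual link (`K_est`, `B_est`, `M_est`) and shapes the command by
#' position, velocity and acceleration of the desired cursor trajectory.
#'
#' @param kind `"delayed_state"` or `"mechanical"`.
#' @param tau_est estimated delay (s), delayed-state kind only.
#' @param K_est,B_est,M_est estimated spring (N/m), damper (N s/m) and mass
#'   (kg), mechanical kind only. `K_est > 0`, `B_est >= 0`, `M_est >= 0`.
#' @return an object of class `representation_state`.
#' @export
representation_state <- function(kind = c("delayed_state", "mechanical"),
                                 tau_est = NULL, K_est = NULL,
                                 B_est = NULL, M_est = NULL) {
  kind <- match.arg(kind)
  if (kind == "delayed_state") {
    if (is.null(tau_est) || !is.finite(tau_est) || tau_est < 0) {
      stop("delayed_state representation needs tau_est >= 0")
    }
    if (!is.null(K_est) || !is.null(B_est) || !is.null(M_est)) {
      stop("mechanical parameters are not used by the delayed_state kind")
    }
    st <- list(kind = kind, tau_est = tau_est)
  } else {
    if (is.null(K_est) || !is.finite(K_est) || K_est <= 0) {
      stop("mechanical representation needs K_est > 0")
    }
    if (is.null(B_est) || B_est < 0 || is.null(M_est) || M_est < 0) {
      stop("mechanical representation needs B_est >= 0 and M_est >= 0")
    }
    if (!is.null(tau_est)) {
      stop("tau_est is not used by the mechanical kind")
    }
    st <- list(kind = kind, K_est = K_est, B_est = B_est, M_est = M_est)
  }
  structure(st, class = "representation_state")
}

#' @export
print.representation_state <- function(x, ...) {
  if (x$kind == "delayed_state") {
    cat(sprintf("<representation_state> delayed-state, tau_est = %.4g s\n",
                x$tau_est))
  } else {
    cat(sprintf(
      "<representation_state> mechanical, K = %.4g N/m, B/K = %.4g s, M/K = %.4g s^2\n",
      x$K_est, x$B_est / x$K_est, x$M_est / x$K_est))
  }
  invisible(x)
}

#' Hand-command transfer of a representation at one frequency
#'
#' Complex gain/phase by which a representation scales and advances the
#' desired (target) sinusoid to form the hand command. The delayed-state kind
#' is a pure phase advance `exp(j*omega*tau_est)`; the mechanical kind is
#' `1 - (M/K) omega^2 + j (B/K) omega`.
#'
#' @param state a `representation_state`.
#' @param omega angular frequency (rad/s).
#' @return list with `gain` and `phase_rad` (positive = hand leads target).
#' @export
representation_transfer <- function(state, omega) {
  stopifnot(inherits(state, "representation_state"))
  if (state$kind == "delayed_state") {
    list(gain = 1, phase_rad = omega * state$tau_est)
  } else {
    tr <- mech_ratio_transfer(state$B_est / state$K_est,
                              state$M_est / state$K_est, omega)
    list(gain = tr$gain, phase_rad = tr$phase_rad)
  }
}

#' Hand trajectory under the delayed-state representation
#'
#' `x_hand(t) = A * sin(omega * (t + tau_est))`: the command is the target
#' advanced by the estimated delay.
#'
#' @param state a `representation_state` of kind `"delayed_state"`.
#' @param motion a `target_motion`.
#' @param t_grid numeric vector of sample times (s), uniform.
#' @return a `sampled_signal`.
#' @export
hand_delayed_state <- function(state, motion, t_grid) {
  stopifnot(inherits(state, "representation_state"))
  if (state$kind != "delayed_state") {
    stop("state is not a delayed_state representation")
  }
  dt <- t_grid[2] - t_grid[1]
  sampled_signal(
    motion$amplitude * sin(motion$omega * (t_grid + state$tau_est)),
    dt = dt, t0 = t_grid[1])
}

#' Hand trajectory under the mechanical representation
#'
#' `x_hand = x_des + (B/K) dx_des + (M/K) d2x_des` with the desired cursor
#' trajectory equal to the target sinusoid; derivatives are evaluated in
#' closed form (no numerical differentiation).
#'
#' @param state a `representation_state` of kind `"mechanical"`.
#' @param motion a `target_motion`.
#' @param t_grid numeric vector of sample times (s), uniform.
#' @return a `sampled_signal`.
#' @export
hand_mechanical_rep <- function(state, motion, t_grid) {
  stopifnot(inherits(state, "representation_state"))
  if (state$kind != "mechanical") {
    stop("state is not a mechanical representation")
  }
  rb <- state$B_est / state$K_est
  rm_ <- state$M_est / state$K_est
  A <- motion$amplitude
  w <- motion$omega
  v <- A * sin(w * t_grid) + rb * A * w * cos(w * t_grid) -
    rm_ * A * w^2 * sin(w * t_grid)
  dt <- t_grid[2] - t_grid[1]
  sampled_signal(v, dt = dt, t0 = t_grid[1])
}

#' Exponential trial-by-trial adaptation schedule
#'
#' `value(i) = c1 + c2 * exp(i / c3)` with `i` the 1-based index of the
#' manipulation trial (familiarization trials do not enter the schedule).
#' With `c3 < 0` the value converges to `c1`. Values are clamped to the
#' physical bounds of the parameter they drive.
#'
#' @param c1,c2,c3 schedule constants (`c3 != 0`).
#' @param applies_to `"tau_est"` (clamped to `[0, 0.5]` s) or `"K_est"`
#'   (clamped to `[1, 500]` N/m).
#' @return an object of class `adaptation_schedule`.
#' @export
adaptation_schedule <- function(c1, c2, c3,
                                applies_to = c("tau_est", "K_est")) {
  applies_to <- match.arg(applies_to)
  if (!is.finite(c3) || c3 == 0) stop("c3 must be nonzero")
  structure(list(c1 = c1, c2 = c2, c3 = c3, applies_to = applies_to),
            class = "adaptation_schedule")
}

#' @export
print.adaptation_schedule <- function(x, ...) {
  cat(sprintf("<adaptation_schedule> %s(i) = %.5g + %.5g * exp(i / %.5g)\n",
              x$applies_to, x$c1, x$c2, x$c3))
  invisible(x)
}

#' Evaluate an adaptation schedule
#' @param schedule an `adaptation_schedule`.
#' @param i trial index (1-based manipulation-trial index), vectorised.
#' @return clamped parameter values.
#' @export
schedule_value <- function(schedule, i) {
  v <- schedule$c1 + schedule$c2 * exp(i / schedule$c3)
  bounds <- if (schedule$applies_to == "tau_est") c(0, 0.5) else c(1, 500)
  pmin(pmax(v, bounds[1]), bounds[2])
}
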