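#' Synthetic-subject parameters
#'
#' Ground-truth description of a simulated participant: which internal
#' representation they use and how it adapts across trials, the kinematic
#' noise on the hand, the carry-over of the compensatory phase lead between
#' trials, and how grip force couples to load force.
#'
#' Defaults emulate the structure the analyses assume: band-limited hand
#' noise (raw white noise would make the differentiated load force blow up,
#' unlike human kinematics), a grip force that slightly leads the load with
#' a multiplicative gain and baseline, and a head-of-trial lead carried over
#' from the previous trial's tail. Noise magnitudes are generator defaults
#' exposed in configuration, not measured human values.
#'
#' @param representation `"mechanical"` or `"delayed_state"`.
#' @param adaptation an `adaptation_schedule` for the representation's
#'   parameter; defaults to near-complete adaptation of the estimated spring
#'   toward the delay-equivalent mechanical parameters (`K -> 27 N/m`).
#' @param B_est,M_est fixed damper/mass estimates of a mechanical-
#'   representation subject; default the delay-equivalent values at
#'   `K = 27 N/m` (`B = 27*0.25`, `M = 27*0.25^2/2`).
#' @param hand_noise_sd band-limited hand noise SD (m).
#' @param noise_cutoff low-pass cutoff of the hand noise (Hz).
#' @param carry_factor head lead of trial i+1 as a fraction of trial i's
#'   tail lead.
#' @param washout fraction of the plateau lead still present at the trial
#'   tail after realignment.
#' @param gf_gain grip/load coupling gain (dimensionless, > 0).
#' @param gf_lead grip-force lead over load force, seconds in `[0, 0.5)`.
#' @param gf_baseline baseline grip force (N).
#' @param gf_noise_sd grip-force noise SD (N).
#' @param gf_floor minimum grip force (N); grip never fully releases.
#' @param gf_target `"total_load"` couples GF to inertial plus virtual
#'   spring load; `"inertial_only"` to the inertial load alone.
#' @param K_true spring constant (N/m) generating the virtual load.
#' @param mass handle mass (kg).
#' @param seed integer seed; generators are pure functions of
#'   (params, seed, trial index).
#' @return an object of class `subject_params`.
#' @export
subject_params <- function(representation = c("mechanical", "delayed_state"),
                           adaptation = NULL, B_est = 27 * 0.25,
                           M_est = 27 * 0.25^2 / 2,
                           hand_noise_sd = 0.002, noise_cutoff = 5,
                           carry_factor = 0.8, washout = 0.5,
                           gf_gain = 2, gf_lead = 0.05, gf_baseline = 1,
                           gf_noise_sd = 0.05, gf_floor = 0.1,
                           gf_target = c("total_load", "inertial_only"),
                           K_true = 27, mass = 0.1, seed = 1) {
  representation <- match.arg(representation)
  gf_target <- match.arg(gf_target)
  if (is.null(adaptation)) {
    adaptation <- if (representation == "mechanical") {
      adaptation_schedule(27, 1300, -1.5, "K_est")
    } else {
      adaptation_schedule(0.25, -0.32, -1.5, "tau_est")
    }
  }
  stopifnot(inherits(adaptation, "adaptation_schedule"))
  if (hand_noise_sd < 0 || gf_noise_sd < 0) stop("noise SDs must be >= 0")
  if (gf_lead < 0 || gf_lead >= 0.5) stop("gf_lead must be in [0, 0.5)")
  if (gf_gain <= 0) stop("gf_gain must be > 0")
  structure(list(representation = representation, adaptation = adaptation,
                 B_est = B_est, M_est = M_est,
                 hand_noise_sd = hand_noise_sd, noise_cutoff = noise_cutoff,
                 carry_factor = carry_factor, washout = washout,
                 gf_gain = gf_gain, gf_lead = gf_lead,
                 gf_baseline = gf_baseline, gf_noise_sd = gf_noise_sd,
                 gf_floor = gf_floor, gf_target = gf_target,
                 K_true = K_true, mass = mass, seed = seed),
            class = "subject_params")
}

#' @export
print.subject_params <- function(x, ...) {
  cat(sprintf(
    "<subject_params> %s representation, hand noise %.3g m, GF lead %.3g s, seed %d\n",
    x$representation, x$hand_noise_sd, x$gf_lead, x$seed))
  invisible(x)
}

band_limited_noise <- function(n, sd, cutoff, fs) {
  if (sd == 0) return(numeric(n))
  w <- stats::rnorm(n)
  bf <- signal::butter(2, cutoff / (fs / 2), type = "low")
  f <- signal::filtfilt(bf, w)
  s <- stats::sd(f)
  if (s == 0) return(numeric(n))
  f * (sd / s)
}

subject_state <- function(params, manip_index) {
  value <- schedule_value(params$adaptation, manip_index)
  if (params$representation == "mechanical") {
    representation_state("mechanical", K_est = value,
                         B_est = params$B_est, M_est = params$M_est)
  } else {
    representation_state("delayed_state", tau_est = value)
  }
}

#' Generate one synthetic trial
#'
#' The hand trajectory follows the subject's internal representation with
#' the within-trial ramp: during the aligned head the hand carries over the
#' lead `lead_head`; as the manipulation ramps up the lead and gain morph to
#' the representation's steady-state compensation; on the ramp down they
#' relax toward the residual tail lead (`washout` fraction of the plateau
#' lead). Band-limited noise is added. The cursor is produced by the actual
#' condition operator, and grip force couples to the (rectified) load with
#' lead, gain, baseline and noise, floored so grip never releases.
#'
#' @param params a `subject_params`.
#' @param condition `"N"`, `"D"` or `"M"`.
#' @param motion a `target_motion`; `schedule` the within-trial profile.
#' @param trial_index protocol trial index (1-based); familiarization trials
#'   pass `manip_index = NA`.
#' @param manip_index manipulation-trial index (1-16) driving the
#'   adaptation schedule, or `NA` for familiarization trials.
#' @param lead_head phase lead (s) carried into the trial head.
#' @param dt sampling step (s).
#' @return list with `trial` (a `trial_record`) and `truth` (ground-truth
#'   sidecar: representation state, steady-state lead and gain, lead
#'   profile per segment, tail lead, grip-force lead, true plateau RMSE of
#'   the noiseless trajectory).
#' @export
generate_trial <- function(params, condition, motion = target_motion(),
                           schedule = delay_schedule(), trial_index = 1,
                           manip_index = NA, lead_head = 0, dt = 1 / 400) {
  stopifnot(inherits(params, "subject_params"))
  condition <- match.arg(condition, c("N", "D", "M"))
  t <- trial_time_grid(schedule, dt)
  n <- length(t)
  fs <- 1 / dt
  w <- motion$omega
  state <- if (is.na(manip_index)) normal_state(params$representation)
           else subject_state(params, manip_index)
  tr <- representation_transfer(state, w)
  lead_ss <- tr$phase_rad / w
  gain_ss <- tr$gain
  lead_tail <- params$washout * lead_ss
  r <- delay_at_time(t, schedule) /
    max(schedule$plateau_value, .Machine$double.eps)
  dur <- trial_duration(schedule)
  lead_edge <- lead_head + (lead_tail - lead_head) * t / dur
  lead_t <- r * lead_ss + (1 - r) * lead_edge
  gain_t <- 1 + (gain_ss - 1) * r
  clean <- gain_t * motion$amplitude * sin(w * (t + lead_t))
  noise <- with_seed(params$seed * 1000L + trial_index, {
    band_limited_noise(n, params$hand_noise_sd, params$noise_cutoff, fs)
  })
  hand <- sampled_signal(clean + noise, dt = dt, t0 = 0)
  cursor <- condition_cursor(hand, condition, schedule)
  lf_inertial <- load_force(hand, mass = params$mass)
  stretch <- hand$values - cursor$values
  lf_target <- if (params$gf_target == "total_load") {
    as_signal_like(lf_inertial$values + params$K_true * stretch, lf_inertial)
  } else lf_inertial
  lf_led <- shift_signal(lf_target, -params$gf_lead)
  gf_clean <- params$gf_gain * abs(lf_led$values) + params$gf_baseline
  gf_noise <- with_seed(params$seed * 1000L + trial_index + 500000L, {
    band_limited_noise(n, params$gf_noise_sd, params$noise_cutoff, fs)
  })
  gf <- pmax(gf_clean + gf_noise, params$gf_floor)
  trial <- trial_record(t, target_position(motion, t), hand$values,
                        cursor$values, grip_force = gf,
                        condition = condition, schedule = schedule)
  seg_len <- 5
  n_seg <- floor(dur / seg_len)
  seg_lead <- vapply(seq_len(n_seg), function(k) {
    idx <- t >= (k - 1) * seg_len & t < k * seg_len
    mean(lead_t[idx])
  }, numeric(1))
  clean_rmse <- sqrt(mean({
    win <- plateau_window(schedule)
    idx <- t >= win[1] - 1e-9 & t < win[2] - 1e-9
    cc <- condition_cursor(sampled_signal(clean, dt = dt, t0 = 0),
                           condition, schedule)
    (target_position(motion, t)[idx] - cc$values[idx])^2
  }))
  truth <- list(state = state, condition = condition,
                lead_ss = lead_ss, gain_ss = gain_ss,
                lead_head = lead_head, lead_tail = lead_tail,
                segment_lead = seg_lead, gf_lead = params$gf_lead,
                gf_gain = params$gf_gain, K_true = params$K_true,
                clean_plateau_rmse = clean_rmse)
  list(trial = trial, truth = truth)
}

#' Generate a synthetic experiment for a whole protocol
#'
#' One trial per protocol slot; the adaptation schedule is indexed by the
#' manipulation-trial number, and the compensatory lead carries over between
#' trials (the head lead of trial i+1 is `carry_factor` times the tail lead
#' of trial i).
#'
#' @param params a `subject_params`.
#' @param protocol a `protocol_spec`.
#' @param motion a `target_motion`; `schedule` the within-trial profile.
#' @param dt sampling step (s).
#' @return an object of class `synthetic_experiment`: list with `trials`
#'   (list of `trial_record`), `truths` (ground-truth sidecars), `summary`
#'   (data.frame with trial, condition, analyzed-free ground truth), and
#'   the generating `params` and `protocol`.
#' @export
generate_experiment <- function(params, protocol, motion = target_motion(),
                                schedule = delay_schedule(), dt = 1 / 400) {
  stopifnot(inherits(params, "subject_params"),
            inherits(protocol, "protocol_spec"))
  n_tr <- length(protocol$conditions)
  trials <- vector("list", n_tr)
  truths <- vector("list", n_tr)
  lead_head <- 0
  for (k in seq_len(n_tr)) {
    res <- generate_trial(params, protocol$conditions[k], motion, schedule,
                          trial_index = k,
                          manip_index = protocol$manip_index[k],
                          lead_head = lead_head, dt = dt)
    trials[[k]] <- res$trial
    truths[[k]] <- res$truth
    lead_head <- params$carry_factor * res$truth$lead_tail
  }
  structure(list(
    trials = trials, truths = truths,
    summary = data.frame(
      trial = seq_len(n_tr), condition = protocol$conditions,
      manip_index = protocol$manip_index,
      lead_ss = vapply(truths, `[[`, numeric(1), "lead_ss"),
      clean_plateau_rmse = vapply(truths, `[[`, numeric(1),
                                  "clean_plateau_rmse")),
    params = params, protocol = protocol),
    class = "synthetic_experiment")
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat(sprintf("<synthetic_experiment> %d trials, %s representation subject\n",
              length(x$trials), x$params$representation))
  print(x$summary, digits = 4)
  invisible(x)
}
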