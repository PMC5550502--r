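#' Fit an adaptation schedule to an observed RMSE series
#'
#' Recovers the exponential trial-by-trial adaptation law from a per-trial
#' plateau-RMSE series by least squares over the dominant-condition
#' manipulation trials only (catch and familiarization trials are excluded
#' from the loss, mirroring how the learning curves are fitted). For the
#' delayed-state kind the free constants are `(a1, a2, a3)` of
#' `tau_est(i) = a1 + a2 exp(i/a3)`; for the mechanical kind they are
#' `(b1, b2, b3)` of `K_est(i) = b1 + b2 exp(i/b3)` together with the fixed
#' damper and mass estimates `B_est`, `M_est`.
#'
#' The predicted RMSE uses the closed-form steady-state plateau error
#' ([predict_plateau_rmse()]), which matches the full simulation to the
#' integrator's accuracy, so the fit is cheap enough for seeded multi-start
#' (the exponential-plus-offset loss has local minima).
#'
#' @param observed_rmse numeric vector of per-trial RMSE (m), one entry per
#'   protocol trial (length 19).
#' @param protocol a `protocol_spec`.
#' @param rep_kind `"delayed_state"` or `"mechanical"`.
#' @param motion a `target_motion`; `delay_sched` the within-trial schedule.
#' @param dt sampling step used for the observed series (s).
#' @param n_starts number of seeded random restarts (default 20).
#' @param seed RNG seed for the restarts.
#' @param unadapted_start anchor the schedule at the un-adapted state before
#'   the first manipulation trial (`value(0) <= 0` for `tau_est`,
#'   `value(0) >= 400 N/m` for `K_est`), reflecting that the representation
#'   is veridical for normal tracking when the manipulation first appears.
#'   Implemented as a one-sided quadratic penalty; on by default.
#' @return an object of class `schedule_fit`: list with `schedule` (an
#'   `adaptation_schedule`), `fixed_params` (mechanical kind), `loss`
#'   (sum of squared residuals on dominant trials), `predicted` (length-19
#'   RMSE series under the fitted schedule) and `rep_kind`.
#' @export
fit_schedule <- function(observed_rmse, protocol,
                         rep_kind = c("delayed_state", "mechanical"),
                         motion = target_motion(),
                         delay_sched = delay_schedule(), dt = 1 / 400,
                         n_starts = 20, seed = 1, unadapted_start = TRUE) {
  rep_kind <- match.arg(rep_kind)
  stopifnot(inherits(protocol, "protocol_spec"))
  y <- as.numeric(observed_rmse)
  if (length(y) != length(protocol$conditions)) {
    stop("observed_rmse length must match the protocol length")
  }
  dom <- dominant_trials(protocol)
  dom_cond <- protocol$dominant
  dom_i <- protocol$manip_index[dom]
  y_dom <- y[dom]

  predict_dom <- function(sched, fixed) {
    vapply(dom_i, function(i) {
      st <- state_for_trial(rep_kind, schedule_value(sched, i), fixed)
      predict_plateau_rmse(st, dom_cond, motion, delay_sched, dt)
    }, numeric(1))
  }

  if (rep_kind == "delayed_state") {
    par_to_model <- function(p) {
      list(sched = adaptation_schedule(p[1], p[2], p[3], "tau_est"),
           fixed = NULL)
    }
    starts <- with_seed(seed, lapply(seq_len(n_starts), function(k) {
      c(stats::runif(1, 0, 0.4), stats::runif(1, -0.5, 0.1),
        -stats::runif(1, 0.5, 8))
    }))
    starts <- c(list(c(0.25, -0.3, -1.5), c(0.25, -0.25, -4), c(0, 0.01, 5)),
                starts)
  } else {
    tau_p <- delay_sched$plateau_value
    # B_est and M_est are parameterized relative to the asymptotic spring b1
    # and the delay-equivalent ratios, on a log scale to stay positive
    par_to_model <- function(p) {
      if (p[1] <= 0) stop("negative asymptotic spring")
      list(sched = adaptation_schedule(p[1], p[2], p[3], "K_est"),
           fixed = list(B_est = exp(p[4]) * tau_p * p[1],
                        M_est = exp(p[5]) * tau_p^2 / 2 * p[1]))
    }
    starts <- with_seed(seed, lapply(seq_len(n_starts), function(k) {
      c(stats::runif(1, 5, 120), stats::runif(1, 50, 600),
        -stats::runif(1, 0.5, 8),
        stats::runif(1, -0.3, 0.3), stats::runif(1, -0.3, 0.3))
    }))
    starts <- c(list(c(27, 1300, -1.5, 0, 0),
                     c(27, 373, -3, 0, 0),
                     c(50, 500, -2, 0, 0)),
                starts)
  }

  start_penalty <- function(sched) {
    if (!unadapted_start) return(0)
    v0 <- sched$c1 + sched$c2  # unclamped value just before trial 1
    if (sched$applies_to == "tau_est") max(0, v0)^2
    else max(0, (400 - v0) / 400)^2
  }

  loss_fn <- function(p) {
    m <- tryCatch(par_to_model(p), error = function(e) NULL)
    if (is.null(m)) return(1e12)
    r <- tryCatch(predict_dom(m$sched, m$fixed) - y_dom,
                  error = function(e) NULL)
    if (is.null(r) || any(!is.finite(r))) return(1e12)
    sum(r^2) + start_penalty(m$sched)
  }

  best <- NULL
  for (p0 in starts) {
    f1 <- tryCatch(stats::optim(p0, loss_fn, method = "Nelder-Mead",
                                control = list(maxit = 2000,
                                               reltol = 1e-14)),
                   error = function(e) NULL)
    if (is.null(f1)) next
    f2 <- tryCatch(stats::nlminb(f1$par, loss_fn,
                                 control = list(iter.max = 500)),
                   error = function(e) NULL)
    cand <- if (!is.null(f2) && f2$objective < f1$value) {
      list(par = f2$par, value = f2$objective)
    } else list(par = f1$par, value = f1$value)
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  if (is.null(best) || !is.finite(best$value)) {
    stop("schedule fit failed to converge from every restart")
  }
  m <- par_to_model(best$par)
  predicted <- vapply(seq_along(y), function(k) {
    mi <- protocol$manip_index[k]
    st <- if (is.na(mi)) normal_state(rep_kind)
          else state_for_trial(rep_kind, schedule_value(m$sched, mi), m$fixed)
    predict_plateau_rmse(st, protocol$conditions[k], motion, delay_sched, dt)
  }, numeric(1))
  structure(list(schedule = m$sched, fixed_params = m$fixed,
                 loss = best$value, predicted = predicted,
                 rep_kind = rep_kind, protocol = protocol),
            class = "schedule_fit")
}

#' @export
print.schedule_fit <- function(x, ...) {
  cat(sprintf("<schedule_fit> %s representation, loss = %.3g m^2\n",
              x$rep_kind, x$loss))
  print(x$schedule)
  if (!is.null(x$fixed_params)) {
    cat(sprintf("  B_est = %.4g N s/m, M_est = %.4g kg\n",
                x$fixed_params$B_est, x$fixed_params$M_est))
  }
  invisible(x)
}
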