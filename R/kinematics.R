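#' Plateau tracking error (RMSE)
#'
#' Root-mean-square target-cursor distance over the trial's 80-s plateau,
#' the window where the manipulation parameter is at its maximum.
#'
#' @param trial a `trial_record`.
#' @return RMSE in metres.
#' @export
plateau_rmse <- function(trial) {
  stopifnot(inherits(trial, "trial_record"))
  win <- plateau_window(trial$schedule)
  if (win[2] <= win[1]) stop("trial schedule has no plateau")
  idx <- trial$t >= win[1] - 1e-9 & trial$t < win[2] - 1e-9
  if (!any(idx)) stop("trial does not contain the plateau window")
  d <- trial$x_target[idx] - trial$x_cursor[idx]
  sqrt(mean(d^2))
}

#' Split a signal into consecutive fixed-length segments
#'
#' The signal duration must be an integer multiple of the segment length;
#' a non-multiple duration is an error (no silent truncation).
#'
#' @param x a `sampled_signal`.
#' @param segment_length segment length in seconds (default 5).
#' @return list of `sampled_signal` segments covering the input.
#' @export
segment_signal <- function(x, segment_length = 5) {
  stopifnot(inherits(x, "sampled_signal"))
  n <- length(x$values)
  dur <- n * x$dt
  n_seg <- dur / segment_length
  if (abs(n_seg - round(n_seg)) > 1e-6) {
    stop("signal duration is not an integer multiple of segment_length")
  }
  n_seg <- as.integer(round(n_seg))
  per <- n %/% n_seg
  lapply(seq_len(n_seg), function(k) {
    i0 <- (k - 1L) * per
    sampled_signal(x$values[(i0 + 1L):(i0 + per)], dt = x$dt,
                   t0 = x$t0 + i0 * x$dt)
  })
}

#' Cross-correlation time lag between two signals
#'
#' Lag (in seconds) maximizing the normalized cross-correlation, searched
#' over integer sample lags within `[-max_lag, max_lag]`. Positive lag means
#' the first argument leads the second (`y(t) ~ x(t - lag)`). Ties are
#' broken toward the smallest absolute lag. Each overlap is correlation-
#' normalized, so amplitude differences do not bias the argmax.
#'
#' @param x,y `sampled_signal`s of equal length and sampling step.
#' @param max_lag search half-window in seconds (< half the signal duration).
#' @return lag in seconds.
#' @export
xcorr_lag <- function(x, y, max_lag = 0.9) {
  stopifnot(inherits(x, "sampled_signal"), inherits(y, "sampled_signal"))
  if (length(x$values) != length(y$values)) stop("signals must have equal length")
  if (abs(x$dt - y$dt) > 1e-12) stop("signals must share the sampling step")
  n <- length(x$values)
  if (stats::sd(x$values) == 0 || stats::sd(y$values) == 0) {
    stop("zero-variance input")
  }
  L <- as.integer(floor(max_lag / x$dt + 1e-9))
  if (L >= n / 2) stop("max_lag must be below half the signal duration")
  xv <- x$values; yv <- y$values
  # Pearson correlation over each overlap, for every lag at once: the raw
  # product sums come from an FFT cross-correlation (convolve(type="open")
  # computes conv(u, rev(v)), so passing xv unreversed cross-correlates,
  # with sum_t x[t]*y[t+l] at index n + l) and the overlap means/variances
  # from prefix sums
  cc_full <- stats::convolve(yv, xv, type = "open")
  lags <- -L:L
  m <- n - abs(lags)
  px <- c(0, cumsum(xv)); px2 <- c(0, cumsum(xv^2))   # px[k+1] = sum x[1:k]
  py <- c(0, cumsum(yv)); py2 <- c(0, cumsum(yv^2))
  pos <- lags >= 0
  Sa <- Sb <- Sa2 <- Sb2 <- numeric(length(lags))
  lp <- lags[pos]; ln <- -lags[!pos]
  Sa[pos] <- px[n - lp + 1];          Sa2[pos] <- px2[n - lp + 1]
  Sb[pos] <- py[n + 1] - py[lp + 1];  Sb2[pos] <- py2[n + 1] - py2[lp + 1]
  Sa[!pos] <- px[n + 1] - px[ln + 1]; Sa2[!pos] <- px2[n + 1] - px2[ln + 1]
  Sb[!pos] <- py[n - ln + 1];         Sb2[!pos] <- py2[n - ln + 1]
  Sab <- cc_full[n + lags]
  va <- Sa2 - Sa^2 / m
  vb <- Sb2 - Sb^2 / m
  cc <- ifelse(va <= 0 | vb <= 0, -Inf,
               (Sab - Sa * Sb / m) / sqrt(va * vb))
  best <- max(cc)
  if (!is.finite(best)) stop("zero-variance overlap at every lag")
  cand <- lags[cc >= best - 1e-12]
  cand[which.min(abs(cand))] * x$dt
}

#' Per-segment lags over a trial
#'
#' Container for the per-segment cross-correlation lags of one trial.
#'
#' @param lags numeric vector of lags (s).
#' @param segment_length segment length (s).
#' @return an object of class `segment_lags`.
#' @export
segment_lags <- function(lags, segment_length = 5) {
  structure(list(lags = as.numeric(lags), segment_length = segment_length),
            class = "segment_lags")
}

#' @export
print.segment_lags <- function(x, ...) {
  cat(sprintf("<segment_lags> %d segments of %g s\n",
              length(x$lags), x$segment_length))
  print(round(x$lags, 4))
  invisible(x)
}

#' Segment-wise lag profile of a trial
#'
#' Splits the trial into consecutive 5-s segments (22 for a 110-s trial) and
#' computes the cross-correlation lag of the cursor (or hand) against the
#' target in each segment. Positive lag means the first signal leads the
#' target.
#'
#' @param trial a `trial_record`.
#' @param which `"cursor_vs_target"` or `"hand_vs_target"`.
#' @param segment_length segment length (s), default 5.
#' @param max_lag cross-correlation search half-window (s), default 0.9
#'   (half the target period, the widest alias-free window).
#' @return a `segment_lags` object.
#' @export
trial_lag_profile <- function(trial,
                              which = c("cursor_vs_target", "hand_vs_target"),
                              segment_length = 5, max_lag = 0.9) {
  stopifnot(inherits(trial, "trial_record"))
  which <- match.arg(which)
  lead_sig <- trial_signal(trial,
                           if (which == "cursor_vs_target") "x_cursor"
                           else "x_hand")
  targ <- trial_signal(trial, "x_target")
  segs_a <- segment_signal(lead_sig, segment_length)
  segs_b <- segment_signal(targ, segment_length)
  lags <- mapply(function(a, b) xcorr_lag(a, b, max_lag), segs_a, segs_b)
  segment_lags(lags, segment_length)
}

#' After-effect of a trial's lag profile
#'
#' Difference between the lag of the last segment under the manipulation
#' (segment 19) and the last segment of the trial where hand and cursor are
#' realigned (segment 22).
#'
#' @param lags a `segment_lags` with exactly 22 entries.
#' @return after-effect in seconds.
#' @export
after_effect <- function(lags) {
  stopifnot(inherits(lags, "segment_lags"))
  if (length(lags$lags) != 22L) stop("after_effect needs exactly 22 segments")
  lags$lags[19] - lags$lags[22]
}

#' Double-exponential learning-curve fit
#'
#' Least-squares fit of `y(i) = p1*exp(-i/p2) + p3*exp(-i/p4) + p5` with
#' `p2, p4 > 0`, by multi-start quasi-Newton optimisation on log-transformed
#' time constants. Nests a single exponential plus offset.
#'
#' @param rmse_by_trial numeric vector of per-trial errors (>= 6 trials).
#' @param n_starts number of seeded random restarts.
#' @param seed RNG seed for the restarts.
#' @return an object of class `learning_curve_fit`: list with `par`
#'   (p1..p5), `r_squared`, `fitted`, and `predict(i)`.
#' @export
fit_learning_curve <- function(rmse_by_trial, n_starts = 20, seed = 1) {
  y <- as.numeric(rmse_by_trial)
  if (length(y) < 6L) stop("need at least 6 trials to fit a learning curve")
  i <- seq_along(y)
  model <- function(p, idx) {
    p[1] * exp(-idx / exp(p[2])) + p[3] * exp(-idx / exp(p[4])) + p[5]
  }
  sse <- function(p) {
    r <- y - model(p, i)
    s <- sum(r^2)
    if (!is.finite(s)) 1e12 else s
  }
  span <- max(diff(range(y)), 1e-12)
  n <- length(y)
  starts <- with_seed(seed, {
    lapply(seq_len(n_starts), function(k) {
      c(stats::runif(1, -1, 1) * span,
        log(stats::runif(1, 0.3, n)),
        stats::runif(1, -1, 1) * span,
        log(stats::runif(1, 0.3, n)),
        y[n] + stats::runif(1, -0.2, 0.2) * span)
    })
  })
  # deterministic starts: fast+slow split and constant
  starts <- c(list(c(span, log(1), span / 2, log(n / 2), y[n]),
                   c(y[1] - y[n], log(2), 0, log(n), y[n]),
                   c(0, log(1), 0, log(n), mean(y))),
              starts)
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      stats::optim(p0, sse, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    fit2 <- tryCatch(stats::nlminb(fit$par, sse,
                                   control = list(iter.max = 500)),
                     error = function(e) NULL)
    cand <- if (!is.null(fit2) && fit2$objective < fit$value) {
      list(par = fit2$par, value = fit2$objective)
    } else list(par = fit$par, value = fit$value)
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  if (is.null(best)) stop("learning-curve fit failed from every start")
  p <- best$par
  par <- c(p1 = p[1], p2 = exp(p[2]), p3 = p[3], p4 = exp(p[4]), p5 = p[5])
  fitted <- model(p, i)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - best$value / ss_tot
  structure(list(par = par, r_squared = r2, fitted = fitted,
                 residual_ss = best$value,
                 predict = function(idx) model(p, idx)),
            class = "learning_curve_fit")
}

#' @export
print.learning_curve_fit <- function(x, ...) {
  cat(sprintf(
    "<learning_curve_fit> y(i) = %.4g exp(-i/%.4g) + %.4g exp(-i/%.4g) + %.4g, R^2 = %.4f\n",
    x$par[1], x$par[2], x$par[3], x$par[4], x$par[5], x$r_squared))
  invisible(x)
}

#' Movement amplitude from reversal points
#'
#' Detects reversal points (alternating local maxima and minima) of a
#' position signal with a prominence threshold and returns the mean absolute
#' displacement of the reversals — the per-trial movement amplitude.
#'
#' @param x_hand a `sampled_signal` covering at least 2 movement cycles.
#' @param prominence minimum swing (m) for a reversal to count; defaults to
#'   10% of the signal's half-range, which rejects noise micro-reversals.
#' @return mean absolute reversal amplitude (m).
#' @export
movement_amplitude <- function(x_hand, prominence = NULL) {
  stopifnot(inherits(x_hand, "sampled_signal"))
  v <- x_hand$values
  if (is.null(prominence)) prominence <- 0.1 * diff(range(v)) / 2
  revs <- find_reversals(v, prominence)
  if (length(revs) < 2L) stop("no movement reversals found")
  mean(abs(v[revs]))
}

# zigzag reversal filter: commits a pivot when the signal retraces more than
# `prominence` from the running extreme; boundary pivots are discarded
find_reversals <- function(v, prominence) {
  n <- length(v)
  revs <- integer(0)
  # unknown direction: track both running extremes until one is retraced
  max_i <- 1L; max_v <- v[1]; min_i <- 1L; min_v <- v[1]
  dir <- 0L; ext_i <- 1L; ext_v <- v[1]
  i <- 2L
  while (i <= n && dir == 0L) {
    if (v[i] > max_v) { max_v <- v[i]; max_i <- i }
    if (v[i] < min_v) { min_v <- v[i]; min_i <- i }
    if (max_v - v[i] > prominence) {
      revs <- c(revs, max_i); dir <- -1L; ext_v <- v[i]; ext_i <- i
    } else if (v[i] - min_v > prominence) {
      revs <- c(revs, min_i); dir <- 1L; ext_v <- v[i]; ext_i <- i
    }
    i <- i + 1L
  }
  while (i <= n) {
    if (dir == 1L) {
      if (v[i] > ext_v) { ext_v <- v[i]; ext_i <- i }
      if (ext_v - v[i] > prominence) {
        revs <- c(revs, ext_i); dir <- -1L; ext_v <- v[i]; ext_i <- i
      }
    } else {
      if (v[i] < ext_v) { ext_v <- v[i]; ext_i <- i }
      if (v[i] - ext_v > prominence) {
        revs <- c(revs, ext_i); dir <- 1L; ext_v <- v[i]; ext_i <- i
      }
    }
    i <- i + 1L
  }
  revs[revs > 1L & revs < n]
}
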