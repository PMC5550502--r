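make_trial <- function(cursor_values, hand_values = NULL, gf = NULL,
                       sch = delay_schedule(), condition = "D") {
  t <- seq(0, trial_duration(sch) - 1 / 400, by = 1 / 400)
  tgt <- 0.06 * sin(OMEGA0 * t)
  if (is.null(hand_values)) hand_values <- tgt
  trial_record(t, tgt, hand_values, cursor_values, grip_force = gf,
               condition = condition, schedule = sch)
}

test_that("plateau_rmse equals its brute-force definition", {
  t <- seq(0, 110 - 1 / 400, by = 1 / 400)
  tgt <- 0.06 * sin(OMEGA0 * t)
  tr <- make_trial(tgt)
  expect_equal(plateau_rmse(tr), 0)
  tr2 <- make_trial(tgt + 0.01)
  expect_equal(plateau_rmse(tr2), 0.01)
  tr3 <- make_trial(0.06 * sin(OMEGA0 * (t - 0.25)))
  expect_equal(plateau_rmse(tr3), sqrt(2) * 0.06 * abs(sin(OMEGA0 * 0.25 / 2)),
               tolerance = 1e-3)
  expect_equal(plateau_rmse(tr3), 0.0359, tolerance = 1e-3)
  expect_equal(plateau_rmse(tr3), brute_rmse(tr3))
})

test_that("segmentation yields exact non-overlapping cover or errors", {
  x <- sin_signal(110)
  segs <- segment_signal(x, 5)
  expect_length(segs, 22)
  expect_true(all(vapply(segs, length, integer(1)) == 2000))
  expect_equal(unlist(lapply(segs, function(s) s$values)), x$values)
  expect_length(segment_signal(sin_signal(10), 5), 2)
  expect_error(segment_signal(sin_signal(11), 5), "multiple")
})

test_that("xcorr_lag recovers constructed shifts against the brute-force oracle", {
  x <- sin_signal(5)
  expect_equal(xcorr_lag(x, x, 0.9), 0)
  y <- apply_delay(x, 40 / 400)
  expect_equal(xcorr_lag(x, y, 0.9), 0.100)
  # the +-0.9 s window excludes the period alias of a 0.25 s phase shift
  t <- signal_time(x)
  y2 <- sampled_signal(sin(OMEGA0 * (t - 0.25)), dt = 1 / 400)
  expect_equal(xcorr_lag(x, y2, 0.9), 0.25)
  expect_equal(brute_lag(x, y2, 0.9), 0.25)
  expect_error(xcorr_lag(x, sampled_signal(rep(1, length(t)), 1 / 400), 0.9),
               "variance")
  expect_error(xcorr_lag(x, y, 3), "half")
})

test_that("xcorr_lag matches the brute-force oracle on random noisy pairs", {
  set.seed(42)
  t <- seq(0, 5 - 1 / 400, by = 1 / 400)
  for (k in 1:10) {
    a <- sampled_signal(sin(OMEGA0 * t + runif(1, 0, 2 * pi)) +
                        0.2 * rnorm(length(t)))
    b <- sampled_signal(sin(OMEGA0 * t + runif(1, 0, 2 * pi)) +
                        0.2 * rnorm(length(t)))
    expect_equal(xcorr_lag(a, b, 0.9), brute_lag(a, b, 0.9))
  }
})

test_that("trial lag profile flags leads and lags per segment", {
  sch <- delay_schedule()
  t <- seq(0, 110 - 1 / 400, by = 1 / 400)
  hand <- 0.06 * sin(OMEGA0 * t)
  cursor <- condition_cursor(sampled_signal(hand, 1 / 400), "D", sch)
  tr <- make_trial(cursor$values, hand_values = hand)
  lags <- trial_lag_profile(tr, "cursor_vs_target")
  expect_length(lags$lags, 22)
  # plateau segments: cursor lags the target by the full delay
  expect_equal(unname(lags$lags[5:18]), rep(-0.25, 14), tolerance = 1e-9)
  # aligned head: no lag
  expect_equal(lags$lags[1], 0)
})

test_that("after_effect is the segment-19 minus segment-22 difference", {
  l <- segment_lags(rep(0.1, 22))
  expect_equal(after_effect(l), 0)
  v <- rep(0, 22); v[19] <- -0.20; v[22] <- 0.05
  expect_equal(after_effect(segment_lags(v)), -0.25)
  # antisymmetry under swapping the two referenced segments
  v2 <- v; v2[19] <- v[22]; v2[22] <- v[19]
  expect_equal(after_effect(segment_lags(v2)), -after_effect(segment_lags(v)))
  expect_error(after_effect(segment_lags(rep(0, 21))), "22")
})

test_that("learning-curve fit recovers known curves", {
  i <- 1:16
  truth <- function(i) 0.03 * exp(-i / 2) + 0.01 * exp(-i / 7) + 0.004
  f <- fit_learning_curve(truth(i), n_starts = 10, seed = 1)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
  expect_lt(max(abs(f$predict(i) - truth(i))), 1e-8)
  expect_lt(abs(f$predict(19) - truth(19)), 1e-8)

  fc <- fit_learning_curve(rep(0.01, 10), n_starts = 4, seed = 1)
  expect_equal(fc$predict(19), 0.01, tolerance = 1e-8)

  fs <- fit_learning_curve(0.05 * exp(-i / 3) + 0.002, n_starts = 10, seed = 1)
  expect_lt(fs$residual_ss, 1e-12)

  expect_error(fit_learning_curve(1:5), "6 trials")
})

test_that("learning-curve extrapolation is continuous in the data", {
  i <- 1:16
  y <- 0.03 * exp(-i / 3) + 0.005
  f0 <- fit_learning_curve(y, n_starts = 8, seed = 3)
  eps <- 1e-5
  y2 <- y; y2[8] <- y2[8] + eps
  f1 <- fit_learning_curve(y2, n_starts = 8, seed = 3)
  expect_lt(abs(f1$predict(19) - f0$predict(19)), 100 * eps)
})

test_that("movement amplitude averages the reversal displacements", {
  x <- sin_signal(110, amp = 0.06)
  expect_equal(movement_amplitude(x), 0.06, tolerance = 1e-4)
  # ideal mechanical-condition hand moves with the larger amplitude
  gain <- sqrt(1 + TAU0^4 * OMEGA0^4 / 4)
  xm <- sin_signal(110, amp = 0.06 * gain)
  expect_equal(movement_amplitude(xm), 0.0642, tolerance = 1e-3)
  # band-limited noise below the prominence threshold barely moves it
  set.seed(7)
  bf <- signal::butter(2, 5 / 200, type = "low")
  noise <- signal::filtfilt(bf, rnorm(length(x$values)))
  noise <- noise * 0.002 / sd(noise)
  xn <- sampled_signal(x$values + noise, 1 / 400)
  expect_equal(movement_amplitude(xn), 0.06, tolerance = 0.02)
  expect_error(movement_amplitude(sampled_signal(seq(0, 1, length.out = 100),
                                                 dt = 0.01)), "reversals")
})
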