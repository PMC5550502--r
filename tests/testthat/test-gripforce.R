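test_that("load_force is mass times filtered acceleration", {
  const <- sampled_signal(rep(0.05, 4000), dt = 1 / 400)
  expect_lt(max(abs(load_force(const, mass = 0.1)$values)), 1e-9)

  x <- sin_signal(20, amp = 0.06)
  lf <- load_force(x, mass = 0.1)
  t <- signal_time(x)
  analytic <- -0.1 * 0.06 * OMEGA0^2 * sin(OMEGA0 * t)
  interior <- t > 1 & t < 19
  expect_equal(max(abs(lf$values[interior])), 0.1 * 0.06 * OMEGA0^2,
               tolerance = 0.01)
  # zero-phase contract: no lag against the analytic acceleration
  expect_equal(xcorr_lag(sampled_signal(analytic[interior], 1 / 400),
                         sampled_signal(lf$values[interior], 1 / 400), 0.4),
               0)
  expect_error(load_force(x, mass = 0), "mass")
  expect_error(load_force(x, cutoff = 300), "Nyquist")
})

test_that("zero-phase filtering leaves band-limited noise unlagged", {
  set.seed(3)
  raw <- stats::rnorm(4000)
  bf <- signal::butter(2, 8 / 200, type = "low")
  smooth <- signal::filtfilt(bf, raw)
  x <- sampled_signal(smooth, dt = 1 / 400)
  xf <- load_force(x, mass = 1)  # differentiate + filter
  # compare filtered acceleration against unfiltered second difference
  acc <- signal_deriv(signal_deriv(x))
  idx <- 200:3800
  expect_equal(xcorr_lag(sampled_signal(acc$values[idx], 1 / 400),
                         sampled_signal(xf$values[idx], 1 / 400), 0.2), 0)
})

test_that("virtual spring force follows the stretch convention", {
  x <- sin_signal(5, amp = 0.02)
  expect_equal(max(abs(virtual_spring_force(x, x, 27)$values)), 0)
  fv <- virtual_spring_force(sampled_signal(rep(0.02, 2000), 1 / 400),
                             sampled_signal(rep(0, 2000), 1 / 400), K = 27)
  expect_equal(fv$values[1], 0.54)
  expect_error(virtual_spring_force(x, x, 0), "K")
})

test_that("gf_lf phase recovers constructed leads and the ratio scales", {
  x <- sin_signal(110, amp = 0.06)
  lf <- load_force(x, mass = 0.1)
  # GF as a rectified copy with a +60 ms constructed lead
  gf_led <- shift_signal(sampled_signal(abs(lf$values), 1 / 400), -0.060)
  expect_equal(gf_lf_phase(gf_led, lf), 0.060, tolerance = 1e-9)
  gf0 <- sampled_signal(abs(lf$values), 1 / 400)
  expect_equal(gf_lf_phase(gf0, lf), 0)

  gf2 <- sampled_signal(2 * abs(lf$values), 1 / 400)
  expect_equal(gf_lf_ratio(gf2, lf), 2)
  # scaling GF scales the ratio
  gf6 <- sampled_signal(3 * gf2$values, 1 / 400)
  expect_equal(gf_lf_ratio(gf6, lf), 3 * gf_lf_ratio(gf2, lf))
  zero_lf <- sampled_signal(rep(0, length(x$values)), 1 / 400)
  expect_error(gf_lf_ratio(gf2, zero_lf), "zero")
})

test_that("gain-plus-baseline grip coupling is recovered by the ratio", {
  x <- sin_signal(110, amp = 0.06)
  lf <- load_force(x, mass = 0.1)
  set.seed(11)
  g <- 1.8; b <- 0.4
  gf <- sampled_signal(g * abs(lf$values) + b +
                       0.01 * stats::rnorm(length(lf$values)), 1 / 400)
  win <- signal_time(lf) >= 15 & signal_time(lf) < 95
  expected <- g + b / mean(abs(lf$values[win]))
  expect_equal(gf_lf_ratio(gf, lf), expected, tolerance = 0.01)
})

test_that("virtual-force correction restores the constructed grip lead", {
  p <- subject_params(hand_noise_sd = 0, gf_noise_sd = 0, seed = 3)
  for (cond in c("D", "M")) {
    g <- generate_trial(p, cond, manip_index = 16, trial_index = 4)
    gm <- grip_metrics(g$trial, mass = p$mass, K = p$K_true)
    # raw phase (vs inertial load alone) exceeds the true lead in magnitude
    expect_gt(abs(gm$phase_s), p$gf_lead)
    # correcting with the true K restores the lead within one sample
    expect_lte(abs(gm$corrected_phase_s - p$gf_lead), 1 / 400 + 1e-9)
    # the virtual force increases the rectified load, shrinking the ratio
    expect_lt(gm$corrected_ratio, gm$ratio)
  }
  # Normal condition: the virtual force vanishes, corrected ~ raw
  gn <- generate_trial(p, "N", manip_index = NA, trial_index = 1)
  gmn <- grip_metrics(gn$trial, mass = p$mass, K = p$K_true)
  expect_equal(gmn$corrected_phase_s, gmn$phase_s, tolerance = 1 / 400)
  expect_equal(gmn$corrected_ratio, gmn$ratio, tolerance = 1e-6)
  expect_error(grip_metrics(gn$trial, K = 0), "K")
})

test_that("grip phases are invariant to the assumed handle mass", {
  p <- subject_params(hand_noise_sd = 0, gf_noise_sd = 0, seed = 5)
  g <- generate_trial(p, "D", manip_index = 16, trial_index = 4)
  m1 <- grip_metrics(g$trial, mass = 0.1, K = p$K_true)
  m2 <- grip_metrics(g$trial, mass = 0.4, K = p$K_true)
  expect_equal(m1$phase_s, m2$phase_s)
  expect_false(isTRUE(all.equal(m1$ratio, m2$ratio)))
})
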