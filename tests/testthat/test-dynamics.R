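test_that("mechanical_from_delay applies the Taylor equalities", {
  p <- mechanical_from_delay(0)
  expect_equal(c(p$ratio_b, p$ratio_m), c(0, 0))
  p <- mechanical_from_delay(0.25)
  expect_equal(c(p$ratio_b, p$ratio_m), c(0.25, 0.03125))
  p <- mechanical_from_delay(0.1)
  expect_equal(c(p$ratio_b, p$ratio_m), c(0.1, 0.005))
  expect_error(mechanical_from_delay(-1), "tau")
})

test_that("delay-derived systems are underdamped with damping ratio 1/sqrt(2)", {
  for (tau in seq(0.05, 0.5, by = 0.05)) {
    p <- mechanical_from_delay(tau)
    zeta <- p$ratio_b / (2 * sqrt(p$ratio_m))
    expect_equal(zeta, 1 / sqrt(2), tolerance = 1e-12)
  }
})

test_that("transfer functions match the closed forms at the operating point", {
  m <- mechanical_transfer(TAU0, OMEGA0)
  expect_equal(round(m$phase_sec, 2), 0.27)
  expect_equal(m$phase_sec, atan(2 * TAU0 * OMEGA0 /
                                 (2 - TAU0^2 * OMEGA0^2)) / OMEGA0)
  expect_equal(m$gain, sqrt(1 + TAU0^4 * OMEGA0^4 / 4))
  expect_equal(m$gain, 1.0702, tolerance = 1e-4)

  d <- delay_transfer(TAU0, OMEGA0)
  expect_equal(d$gain, 1)
  expect_equal(d$phase_sec, 0.25)
  expect_equal(d$phase_rad, TAU0 * OMEGA0)

  z <- mechanical_transfer(0, OMEGA0)
  expect_equal(c(z$gain, z$phase_rad, z$phase_sec), c(1, 0, 0))
  z <- delay_transfer(0, OMEGA0)
  expect_equal(c(z$gain, z$phase_rad, z$phase_sec), c(1, 0, 0))
})

test_that("mechanical phase uses the quadrant-correct arctangent", {
  # real part changes sign at tau*omega = sqrt(2); phase must keep growing
  tau <- 0.25
  w <- seq(2, 12, by = 0.25)
  ph <- mechanical_transfer(tau, w)$phase_rad
  expect_true(all(diff(ph) > 0))
  expect_gt(max(ph), pi / 2)  # beyond where plain atan would wrap
})

test_that("bode_data limits and ordering", {
  grid <- 2 * pi * seq(0.01, 2, length.out = 120)
  b <- bode_data(TAU0, grid)
  expect_true(all(b$delay$gain == 1))
  expect_true(all(diff(b$mechanical$gain) >= 0))
  expect_true(all(b$delay$phase_rad > 0))
  expect_true(all(b$mechanical$phase_rad > 0))
  # omega -> 0: both gains -> 1, both phase_sec -> tau
  expect_equal(b$mechanical$gain[1], 1, tolerance = 1e-3)
  expect_equal(b$mechanical$phase_sec[1], TAU0, tolerance = 1e-3)
  expect_equal(b$delay$phase_sec[1], TAU0)
  # at the operating point the mechanical gain exceeds the delay gain
  m <- mechanical_transfer(TAU0, OMEGA0)
  expect_gt(m$gain, 1)
  # small-tau*omega consistency bound from the arctan expansion
  small <- grid[grid * TAU0 < 0.5]
  ms <- mechanical_transfer(TAU0, small)
  expect_true(all(ms$phase_sec > TAU0 * (1 - TAU0^2 * small^2 / 6)))
  expect_error(bode_data(TAU0, c(1, 0.5)), "increasing")
  expect_error(bode_data(TAU0, c(-1, 1)), "positive")
})

test_that("simulate_mechanical_cursor degenerate and equilibrium cases", {
  x <- sin_signal(5)
  expect_identical(simulate_mechanical_cursor(x, mechanical_params(0, 0))$values,
                   x$values)
  const <- sampled_signal(rep(0.03, 2000), dt = 1 / 400)
  cur <- simulate_mechanical_cursor(const, mechanical_from_delay(0.25),
                                    init_pos = 0)
  expect_equal(cur$values[2000], 0.03, tolerance = 1e-6)
  expect_error(mechanical_params(-0.1, 0), "ratio_b")
})

test_that("ODE steady state matches the transfer function at 400 Hz", {
  x <- sin_signal(40, amp = AMP0)
  cur <- simulate_mechanical_cursor(x, mechanical_from_delay(TAU0))
  ph <- measure_phasor(cur, OMEGA0, from = 20)
  H <- mechanical_transfer(TAU0, OMEGA0)
  expect_equal(ph$amp, AMP0 / H$gain, tolerance = 1e-4)
  # cursor lags hand by 0.27 s (2-decimal rounding of the analytic phase)
  expect_lt(abs(-ph$phase / OMEGA0 - H$phase_sec), 0.002)
  expect_equal(round(-ph$phase / OMEGA0, 2), 0.27)
})

test_that("ODE-transfer equivalence holds across tau and omega", {
  for (tau in c(0.05, 0.2, 0.35, 0.5)) {
    for (w in OMEGA0 * c(0.5, 1, 2)) {
      if (tau * w >= 1) next
      x <- sin_signal(30, omega = w, amp = AMP0)
      cur <- simulate_mechanical_cursor(x, mechanical_from_delay(tau))
      ph <- measure_phasor(cur, w, from = 15)
      H <- mechanical_transfer(tau, w)
      expect_equal(ph$amp * H$gain / AMP0, 1, tolerance = 0.01)
      expect_lt(abs(-ph$phase / w - H$phase_sec), 0.002)
    }
  }
})

test_that("condition_cursor honours the within-trial ramp", {
  sch <- delay_schedule()
  t <- seq(0, 110 - 1 / 400, by = 1 / 400)
  hand <- sampled_signal(AMP0 * sin(OMEGA0 * t), dt = 1 / 400)
  expect_identical(condition_cursor(hand, "N", sch)$values, hand$values)

  cd <- condition_cursor(hand, "D", sch)
  # aligned head: identity; plateau: exact 0.25 s delay
  expect_equal(cd$values[t < 5], hand$values[t < 5])
  plateau <- t >= 20 & t < 95
  expect_equal(cd$values[plateau], AMP0 * sin(OMEGA0 * (t[plateau] - 0.25)),
               tolerance = 1e-9)

  cm <- condition_cursor(hand, "M", sch)
  expect_equal(cm$values[t < 5], hand$values[t < 5], tolerance = 1e-9)
  ph <- measure_phasor(sampled_signal(cm$values[plateau], 1 / 400), OMEGA0,
                       from = 10)
  H <- mechanical_transfer(TAU0, OMEGA0)
  expect_equal(ph$amp, AMP0 / H$gain, tolerance = 1e-3)
})
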