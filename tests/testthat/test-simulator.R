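test_that("delayed-state hand command is the advanced target", {
  mo <- target_motion()
  t <- seq(0, 10 - 1 / 400, by = 1 / 400)
  h0 <- hand_delayed_state(representation_state("delayed_state", tau_est = 0),
                           mo, t)
  expect_equal(h0$values, target_position(mo, t))
  h <- hand_delayed_state(representation_state("delayed_state", tau_est = 0.25),
                          mo, t)
  expect_equal(h$values, 0.06 * sin(OMEGA0 * (t + 0.25)))
  expect_error(hand_delayed_state(
    representation_state("mechanical", K_est = 27, B_est = 1, M_est = 0.1),
    mo, t), "delayed_state")
})

test_that("mechanical hand command uses closed-form derivatives", {
  mo <- target_motion()
  t <- seq(0, 10 - 1 / 400, by = 1 / 400)
  z <- hand_mechanical_rep(
    representation_state("mechanical", K_est = 27, B_est = 0, M_est = 0),
    mo, t)
  expect_equal(z$values, target_position(mo, t))
  st <- representation_state("mechanical", K_est = 27,
                             B_est = 27 * 0.25, M_est = 27 * 0.03125)
  h <- hand_mechanical_rep(st, mo, t)
  expect_equal(h$values,
               0.06 * (sin(OMEGA0 * t) + 0.25 * OMEGA0 * cos(OMEGA0 * t) -
                       0.03125 * OMEGA0^2 * sin(OMEGA0 * t)),
               tolerance = 1e-12)
  expect_error(representation_state("mechanical", K_est = 0, B_est = 1,
                                    M_est = 1), "K_est")
})

test_that("matched representations cancel their own condition", {
  mo <- target_motion(); sch <- delay_schedule()
  # delayed-state with the true delay cancels the Delay condition
  st_d <- representation_state("delayed_state", tau_est = 0.25)
  expect_lt(run_trial(st_d, "D", mo, sch)$rmse, 1e-3 * mo$amplitude)
  # ... but not the Mechanical condition (gain mismatch remains)
  expect_gt(run_trial(st_d, "M", mo, sch)$rmse, 1e-3 * mo$amplitude)

  # mechanical representation with the true ratios cancels Mechanical
  st_m <- representation_state("mechanical", K_est = 27,
                               B_est = default_fixed$B_est,
                               M_est = default_fixed$M_est)
  expect_lt(run_trial(st_m, "M", mo, sch)$rmse, 0.01 * mo$amplitude)
  # ... but leaves the third-order Taylor remainder on Delay
  r_cross <- run_trial(st_m, "D", mo, sch)$rmse
  expect_gt(r_cross, 1e-3 * mo$amplitude)
})

test_that("run_trial plateau RMSE matches the two-sinusoid closed form", {
  mo <- target_motion(); sch <- delay_schedule()
  st0 <- representation_state("delayed_state", tau_est = 0)
  expect_lt(run_trial(st0, "N", mo, sch)$rmse, 1e-12)
  r <- run_trial(st0, "D", mo, sch)
  closed <- sqrt(2) * mo$amplitude * abs(sin(OMEGA0 * TAU0 / 2))
  expect_equal(r$rmse, closed, tolerance = 1e-3)
  expect_equal(r$rmse, brute_rmse(r$trial))
})

test_that("predict_plateau_rmse agrees with the full simulation", {
  mo <- target_motion(); sch <- delay_schedule()
  states <- list(
    representation_state("delayed_state", tau_est = 0.1),
    representation_state("delayed_state", tau_est = 0.25),
    representation_state("mechanical", K_est = 40,
                         B_est = default_fixed$B_est,
                         M_est = default_fixed$M_est))
  for (st in states) {
    for (cond in c("D", "M")) {
      expect_lt(abs(run_trial(st, cond, mo, sch)$rmse -
                    predict_plateau_rmse(st, cond, mo, sch)), 2e-6)
    }
  }
})

test_that("run_protocol: converged schedules sit at the floor and normals stay clean", {
  prot <- protocol_spec(group = 2)
  sched <- adaptation_schedule(27, 0, -1, "K_est")  # already converged
  sim <- run_protocol(prot, "mechanical", sched, default_fixed,
                      method = "closed_form")
  dom <- dominant_trials(prot)
  expect_lt(max(sim$summary$rmse[dom]), 1e-3 * 0.06)
  expect_lt(diff(range(sim$summary$rmse[dom])), 1e-6)
  # familiarization trials do not enter schedules and are error-free
  expect_equal(sim$summary$rmse[1:3], rep(0, 3), tolerance = 1e-12)
  expect_true(all(is.na(sim$summary$param_value[1:3])))
})

test_that("catch-trial asymmetry has the expected signs with the true schedule", {
  sched <- adaptation_schedule(27, 1300, -1.5, "K_est")
  sim2 <- run_protocol(protocol_spec(group = 2), "mechanical", sched,
                       default_fixed, method = "closed_form")
  sim1 <- run_protocol(protocol_spec(group = 1), "mechanical", sched,
                       default_fixed, method = "closed_form")
  expect_gt(catch_trial_contrast(sim2)$mean_diff, 0)
  expect_lte(catch_trial_contrast(sim1)$mean_diff, 0)
})

test_that("fit_schedule recovers a known delayed-state schedule exactly", {
  prot <- protocol_spec(group = 1)
  true_sched <- adaptation_schedule(0.25, -0.32, -1.5, "tau_est")
  obs <- run_protocol(prot, "delayed_state", true_sched,
                      method = "closed_form")
  fit <- fit_schedule(obs$summary$rmse, prot, "delayed_state",
                      n_starts = 8, seed = 1)
  dom <- dominant_trials(prot)
  expect_lt(max(abs(fit$predicted[dom] - obs$summary$rmse[dom])), 1e-6)
})

test_that("a constant RMSE series is fitted by a flat schedule", {
  prot <- protocol_spec(group = 1)
  st <- representation_state("delayed_state", tau_est = 0.1)
  flat <- predict_plateau_rmse(st, "D", target_motion(), delay_schedule())
  y <- rep(flat, 19); y[1:3] <- 0
  fit <- fit_schedule(y, prot, "delayed_state", n_starts = 6, seed = 2)
  dom <- dominant_trials(prot)
  expect_lt(max(abs(fit$predicted[dom] - flat)), 1e-6)
})

test_that("fit_schedule is deterministic given a seed", {
  prot <- protocol_spec(group = 1)
  true_sched <- adaptation_schedule(0.25, -0.32, -1.5, "tau_est")
  obs <- run_protocol(prot, "delayed_state", true_sched,
                      method = "closed_form")
  f1 <- fit_schedule(obs$summary$rmse, prot, "delayed_state",
                     n_starts = 4, seed = 9)
  f2 <- fit_schedule(obs$summary$rmse, prot, "delayed_state",
                     n_starts = 4, seed = 9)
  expect_identical(f1$predicted, f2$predicted)
  expect_identical(f1$schedule$c1, f2$schedule$c1)
})

test_that("protocol definitions match the group designs", {
  p1 <- protocol_spec(group = 1)
  expect_length(p1$conditions, 19)
  expect_equal(p1$conditions[1:3], rep("N", 3))
  expect_equal(p1$dominant, "D")
  expect_equal(p1$catch_trials, c(10, 14, 18))  # manipulation 7, 11, 15
  expect_equal(protocol_spec(group = 2)$dominant, "M")
  p3 <- protocol_spec(group = 3)
  expect_equal(p3$conditions[4:11], rep("D", 8))
  expect_equal(p3$conditions[12:19], rep("M", 8))
  p4 <- protocol_spec(group = 4)
  expect_equal(p4$conditions[4:11], rep("M", 8))
  expect_error(protocol_spec(group = 5), "group")
  expect_error(protocol_spec(conditions = rep("D", 19)), "Normal")
})
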