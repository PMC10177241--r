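test_that("kinetic and potential energy follow their defining formulas", {
  expect_equal(kinetic_energy(80, 0.6), 14.4)
  expect_equal(kinetic_energy(80, 0), 0)
  expect_equal(kinetic_energy(80, -0.6), kinetic_energy(80, 0.6))
  expect_equal(potential_energy(80, 0.10), 78.48)
  expect_equal(potential_energy(80, 0.2), 2 * potential_energy(80, 0.1))
  expect_error(kinetic_energy(-1, 1))
})

test_that("percent recovery matches hand enumeration of positive increments", {
  EK <- c(0, 2, 1, 3); EP <- c(1, 0, 2, 1)
  r <- percent_recovery(EK, EP)
  expect_equal(r$delta_EK, oracle_positive_increments(EK))
  expect_equal(r$delta_EP, oracle_positive_increments(EP))
  expect_equal(r$delta_ET, oracle_positive_increments(EK + EP))
  expect_equal(r$percent_recovery, oracle_recovery(EK, EP))
  # frozen oracle values: dEK = 4, dEP = 2, dET = 3 -> 100 * 3 / 6
  expect_identical(r$percent_recovery, 50)
})

test_that("recovery is 100% for antiphase and 0% for in-phase profiles", {
  t <- seq(0, 2, by = 0.01)
  A <- 5
  EK <- A * (1 + sin(2 * pi * t))
  EP_anti <- A * (1 - sin(2 * pi * t))
  expect_equal(percent_recovery(EK, EP_anti)$percent_recovery, 100,
               tolerance = 1e-9)
  expect_equal(percent_recovery(EK, EK)$percent_recovery, 0,
               tolerance = 1e-9)
})

test_that("recovery ignores the potential-energy datum and stays within [0, 100]", {
  set.seed(14)
  for (i in 1:50) {
    EK <- cumsum(rnorm(40))^2
    EP <- abs(cumsum(rnorm(40)))
    r <- percent_recovery(EK, EP)$percent_recovery
    expect_gte(r, 0); expect_lte(r, 100)
    shift <- runif(1, -100, 100)
    expect_equal(percent_recovery(EK, EP + shift)$percent_recovery, r)
  }
  expect_error(percent_recovery(rep(1, 5), rep(2, 5)), "flat")
})

test_that("phase shift between EP and EK moves recovery from 100% to 0% monotonically", {
  t <- seq(0, 1, by = 0.002)
  EK <- 3 * (1 + sin(2 * pi * t))
  shifts <- seq(0, 0.5, by = 0.1)   # fraction of a period
  recs <- vapply(shifts, function(s) {
    EP <- 3 * (1 - sin(2 * pi * (t - s)))
    percent_recovery(EK, EP)$percent_recovery
  }, numeric(1))
  expect_equal(recs[1], 100, tolerance = 1e-6)
  expect_equal(recs[length(recs)], 0, tolerance = 1e-6)
  expect_true(all(diff(recs) < 0))
})

test_that("the expected period follows the square-root pendulum law", {
  expect_equal(expected_period(0.9942), 2.000, tolerance = 5e-4)
  expect_equal(expected_period(4 * 1.3), 2 * expected_period(1.3))
  # amplitude has no seat in the formula: one argument, length only
  expect_identical(names(formals(expected_period)), c("L", "g"))
})

test_that("observed period is the mean stride duration", {
  expect_equal(observed_period(stride_events("l", 0, 0.62, 0.94)), 0.94)
  # stance 0.85 + swing 0.53 reproduces the printed 1.39 within rounding
  expect_equal(observed_period(stride_events("l", 0, 0.85, 1.38)), 1.38)
  expect_lt(abs(1.38 - 1.39), 0.011)
  # simulated trials: equals the pivot-exchange interval by construction
  truth <- simulate_pendulum_trial(sim_config(L = 1, n_strides = 3))
  ev <- truth$stride_events
  expect_equal(observed_period(ev),
               2 * mean(diff(ev$touchdown_s)), tolerance = 1e-9)
})

test_that("excursions are positional ranges within the stride", {
  t <- seq(0, 1, by = 0.01)
  pos <- cbind(t, 0.1 * sin(2 * pi * t), -1)
  e <- excursions(pos)
  expect_equal(e$ml_excursion_m, 0.2, tolerance = 1e-4)
  expect_equal(e$vertical_excursion_m, 0)
  expect_equal(excursions(matrix(1, 5, 3))$ml_excursion_m, 0)

  # pendulum geometry: vertical excursion is L (1 - cos amplitude)
  L <- 1.1; amp <- 0.3
  truth <- simulate_pendulum_trial(
    sim_config(L = L, amplitude0 = amp, n_strides = 2, sample_rate = 500))
  ev <- truth$stride_events[!is.na(truth$stride_events$next_touchdown_s), ]
  idx <- which(truth$time >= ev$touchdown_s[1] &
                 truth$time < ev$next_touchdown_s[1])
  ee <- excursions(truth$position, idx)
  expect_equal(ee$vertical_excursion_m, L * (1 - cos(amp)), tolerance = 1e-4)
})

test_that("energy profiles are internally consistent and conserve ideal trials", {
  # stationary input
  kin0 <- list(time = 0:10 / 10, velocity = matrix(0, 11, 3),
               position = matrix(rep(c(0, 0, -1), each = 11), 11, 3))
  p0 <- energy_profile(kin0, 80)
  expect_true(all(p0$EK_total == 0))
  expect_equal(diff(range(p0$EP)), 0)
  expect_error(energy_profile(kin0, NULL), "mass")

  # undamped simulated pendulum: ET constant to 1e-6 relative
  truth <- simulate_pendulum_trial(
    sim_config(L = 1, amplitude0 = 0.3, n_strides = 2, sample_rate = 1000))
  kin <- list(time = truth$time, velocity = truth$velocity,
              position = truth$position)
  prof <- energy_profile(kin, truth$config$mass)
  expect_true(all(prof$ET == prof$EK_total + prof$EP))
  expect_lt(diff(range(prof$ET)) / max(prof$ET), 1e-6)

  # human-like damped, driven trial: recovery strictly inside (0, 100)
  cfg <- sim_config(L = 1.2, damping = 2, drive_impulse = 0.5,
                    ml_sway_amplitude = 0.1, n_strides = 3)
  tr <- simulate_pendulum_trial(cfg)
  ev <- tr$stride_events[!is.na(tr$stride_events$next_touchdown_s), ]
  i <- nrow(ev)
  idx <- which(tr$time >= ev$touchdown_s[i] & tr$time < ev$next_touchdown_s[i])
  prof2 <- energy_profile(list(time = tr$time[idx],
                               velocity = tr$velocity[idx, ],
                               position = tr$position[idx, ]), 80)
  rec <- percent_recovery(prof2$EK_total, prof2$EP)$percent_recovery
  expect_gt(rec, 0); expect_lt(rec, 100)
})
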