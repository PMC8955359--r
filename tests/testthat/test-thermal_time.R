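test_that("thermal-time constants and rates follow the defining products", {
  expect_equal(thermal_time_sub(25, 5, 80), 1600)
  expect_equal(thermal_time_sub(25, 5, 48), 960)
  expect_equal(thermal_time_sub(15, 15, 10), 0)
  expect_error(thermal_time_sub(4, 5, 10), class = "seedhtt_domain_error")

  expect_equal(thermal_time_supra(30, 5, 80), 2000)
  expect_equal(thermal_time_supra(30, 5, 96), 2400)
  expect_equal(thermal_time_supra(30, 30, 10), 0)
  expect_error(thermal_time_supra(30, 31, 10), class = "seedhtt_domain_error")

  expect_equal(gr_from_thermal(25, 5, 1600), 0.0125)
  expect_equal(round_half_up(gr_from_thermal(25, 5, 1600), 3), 0.013)
  expect_equal(gr_from_thermal(5, 5, 1600), 0)
  expect_equal(gr_from_thermal(25, 5, 960), 20 / 960)
  expect_error(gr_from_thermal(25, 5, 0), class = "seedhtt_domain_error")
})

test_that("thermal time and rate are mutually inverse", {
  set.seed(1)
  for (i in 1:20) {
    T <- runif(1, 6, 35)
    Tb <- runif(1, 0, 5)
    tg <- runif(1, 1, 200)
    expect_equal(gr_from_thermal(T, Tb, thermal_time_sub(T, Tb, tg)),
                 1 / tg, tolerance = 1e-12)
  }
})

test_that("half-up rounding matches printed germination rates", {
  expect_equal(round_half_up(0.0125, 3), 0.013)   # round() would give 0.012
  expect_equal(round_half_up(0.015625, 2), 0.02)
  expect_equal(round_half_up(0.020833, 3), 0.021)
  expect_equal(round_half_up(0.010417, 3), 0.010)
})

test_that("the reference constants table reconstructs from theta_T1 alone", {
  ref <- eruca_constants()
  rec <- reconstruct_rate_table(ref$theta_T1)
  expect_equal(rec$theta_T2, ref$theta_T2)
  expect_equal(rec$theta_H, ref$theta_H)
  expect_equal(rec$theta_HTT, ref$theta_HTT)
  expect_equal(rec$gr_hydrotime, ref$gr_hydrotime)
  expect_equal(rec$gr_thermal, ref$gr_thermal)
  # the fixed ranges force constant column ratios in every row
  expect_equal(ref$theta_T2 / ref$theta_T1, rep(1.25, 20))
  expect_equal(ref$theta_HTT / ref$theta_H, rep(20, 20))
})

test_that("noise-free rates recover the generating line exactly", {
  temps <- c(10, 15, 20, 30)
  fit <- suppressWarnings(estimate_cardinal_temperatures(
    data.frame(temperature_C = temps, gr = (temps - 5) / 1600)))
  expect_equal(fit$Tb, 5, tolerance = 1e-9)
  expect_equal(fit$theta_T1, 1600, tolerance = 1e-6)
  expect_equal(fit$To, 30)
  expect_equal(fit$Tc, 30)
  expect_true(is.na(fit$theta_T2))
})

test_that("a two-limb tent recovers base, optimum and ceiling", {
  temps <- c(10, 15, 20, 25, 30, 33)
  gr <- ifelse(temps <= 25, (temps - 5) / 1000, (35 - temps) / 500)
  fit <- suppressWarnings(
    estimate_cardinal_temperatures(data.frame(temperature_C = temps,
                                              gr = gr)))
  expect_equal(fit$Tb, 5, tolerance = 1e-9)
  expect_equal(fit$To, 25, tolerance = 1e-9)
  expect_equal(fit$Tc, 35, tolerance = 1e-9)
  expect_equal(fit$theta_T1, 1000, tolerance = 1e-6)
  expect_equal(fit$theta_T2, 500, tolerance = 1e-6)
})

test_that("cardinal temperatures are invariant to rescaling the rates", {
  temps <- c(10, 15, 20, 25, 30, 33)
  gr <- ifelse(temps <= 25, (temps - 5) / 1000, (35 - temps) / 500)
  f1 <- suppressWarnings(
    estimate_cardinal_temperatures(data.frame(temperature_C = temps,
                                              gr = gr)))
  f2 <- suppressWarnings(
    estimate_cardinal_temperatures(data.frame(temperature_C = temps,
                                              gr = 3 * gr)))
  expect_equal(f2$Tb, f1$Tb, tolerance = 1e-9)
  expect_equal(f2$To, f1$To, tolerance = 1e-9)
  expect_equal(f2$Tc, f1$Tc, tolerance = 1e-9)
  expect_equal(f2$theta_T1, f1$theta_T1 / 3, tolerance = 1e-9)
  expect_equal(f2$theta_T2, f1$theta_T2 / 3, tolerance = 1e-9)
})

test_that("degenerate rate patterns raise estimation errors", {
  expect_error(estimate_cardinal_temperatures(
    data.frame(temperature_C = c(10, 20, 30), gr = c(0.02, 0.02, 0.02))),
    class = "seedhtt_domain_error")
  expect_error(estimate_cardinal_temperatures(
    data.frame(temperature_C = 10, gr = 0.02)),
    class = "seedhtt_domain_error")
})

test_that("Tb is recovered within a degree from simulated experiments", {
  # 2 h scoring so that percentile times at warm temperatures are resolved
  tb <- vapply(1:20, function(i) {
    grid <- simulate_experiment(simulation_config(
      seed = 4000 + i, scoring_times = seq(2, 96, by = 2)))
    fit_thermal_time(grid, psi = 0)$Tb
  }, numeric(1))
  expect_lt(abs(median(tb) - 5), 1)
})
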