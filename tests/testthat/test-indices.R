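test_that("single-index worked examples evaluate to their closed forms", {
  expect_equal(germination_percentage(40, 40), 100)
  expect_equal(germination_percentage(0, 40), 0)
  expect_equal(germination_percentage(38, 40), 95)
  expect_error(germination_percentage(10, 0), class = "seedhtt_domain_error")

  expect_equal(mean_germination_time(5, 2), 2)
  expect_equal(mean_germination_time(c(2, 2), c(1, 3)), 2)
  expect_equal(mean_germination_time(c(3, 1), c(2, 4)), 2.5)
  expect_true(is.na(mean_germination_time(c(0, 0), c(1, 2))))

  expect_equal(mean_germination_rate(1), 1)
  expect_equal(mean_germination_rate(2.5), 0.4)
  expect_equal(mean_germination_rate(4), 0.25)
  expect_true(is.na(mean_germination_rate(NA_real_)))

  expect_equal(germination_energy(10, 1), 10)
  expect_equal(germination_energy(c(4, 10), c(1, 2)), 7)
  expect_equal(germination_energy(c(0, 8), c(1, 2)), 4)

  expect_equal(coefficient_velocity_germination(10, 1), 100)
  expect_equal(coefficient_velocity_germination(c(5, 5), c(1, 2)),
               100 * 10 / 15)
  expect_equal(coefficient_velocity_germination(10, 4), 25)
  expect_true(is.na(coefficient_velocity_germination(0, 1)))

  expect_equal(coefficient_variation_time(c(2, 2, 2)), 0)
  expect_equal(coefficient_variation_time(c(1, 3)), 100 * sqrt(2) / 2)
  expect_equal(coefficient_variation_time(c(2, 2, 4)),
               100 * sd(c(2, 2, 4)) / (8 / 3))
  expect_true(is.na(coefficient_variation_time(3)))

  expect_equal(germination_index(c(5, 0, 0, 0), 1:4), 50)
  expect_equal(germination_index(c(0, 0, 0, 5), 1:4), 35)
  expect_equal(germination_index(c(0, 0, 0, 0), 1:4), 0)
  # weights clip at 1 beyond the 10-day ladder
  expect_equal(germination_index(c(2, 3), c(10, 12)), 2 + 3)

  expect_equal(germination_rate_index(100, 1), 100)
  expect_equal(germination_rate_index(c(50, 50), c(1, 2)), 75)
  expect_equal(germination_rate_index(100, 4), 25)

  expect_equal(root_shoot_ratio(0.2, 0.4), 0.5)
  expect_equal(root_shoot_ratio(0.3, 0.3), 1)
  expect_equal(root_shoot_ratio(0, 0.4), 0)
  expect_true(is.na(root_shoot_ratio(0.2, 0)))

  svi <- seed_vigor_indices(10, 2, 95)
  expect_equal(svi$svi1, 950)
  expect_equal(seed_vigor_indices(10, 2, 50)$svi2, 100)
  expect_equal(unlist(seed_vigor_indices(10, 2, 0)),
               c(svi1 = 0, svi2 = 0))
})

test_that("T50 interpolates between the bracketing adjacent counts", {
  expect_equal(as.numeric(time_to_50(20, c(10, 18), c(2, 3))), 2)
  expect_equal(as.numeric(time_to_50(20, c(8, 12), c(2, 3))), 2.5)
  expect_equal(as.numeric(time_to_50(40, c(12, 28), c(1, 2))), 1.5)
  # first count already beyond half: interpolate from the origin, flagged
  t50 <- time_to_50(20, c(16, 20), c(1, 2))
  expect_equal(as.numeric(t50), 10 / 16)
  expect_true(attr(t50, "from_origin"))
  expect_error(time_to_50(0, c(0, 0), c(1, 2)),
               class = "seedhtt_domain_error")
})

test_that("a full report matches applying each single-index op", {
  grid <- simulate_experiment(simulation_config(seed = 3))
  course <- time_courses(grid)[["30.0.1"]]
  report <- compute_index_report(course)

  days <- course$time_h / 24
  cum <- course$cum_germinated
  inc <- diff(c(0, cum))
  n <- course$n_sown[1]
  expect_equal(report$GP, germination_percentage(cum[length(cum)], n))
  expect_equal(report$GE, germination_energy(cum, days))
  expect_equal(report$MGT, mean_germination_time(inc, days))
  expect_equal(report$MGR, mean_germination_rate(report$MGT))
  expect_equal(report$CVt, coefficient_variation_time(rep(days, inc)))
  expect_equal(report$CVG, coefficient_velocity_germination(inc, days))
  expect_equal(report$GI, germination_index(inc, days))
  expect_equal(report$GRI, germination_rate_index(100 * inc / n, days))
  expect_equal(report$T50,
               as.numeric(time_to_50(cum[length(cum)], cum, days)))
})

test_that("an all-zero course reports GP 0, GI 0 and missing time indices", {
  report <- compute_index_report(make_course(c(24, 48, 72, 96), rep(0, 4)))
  expect_equal(report$GP, 0)
  expect_equal(report$GI, 0)
  expect_equal(report$GE, 0)
  expect_equal(report$GRI, 0)
  expect_true(all(is.na(report[c("MGT", "MGR", "CVt", "CVG", "T50")])))
})

test_that("single-day full germination on day d gives the closed forms", {
  for (d in c(1, 2, 4)) {
    course <- make_course(24 * seq_len(4), c(rep(0, d - 1), rep(40, 5 - d)))
    report <- compute_index_report(course)
    expect_equal(report$GP, 100)
    expect_equal(report$MGT, d)
    expect_equal(report$MGR, 1 / d)
    expect_equal(report$CVt, 0)
    expect_equal(report$CVG, 100 / d)
  }
})

test_that("MGR x MGT = 1 whenever both are defined", {
  grid <- simulate_experiment(simulation_config(seed = 5))
  reports <- compute_indices(grid, average = FALSE)
  defined <- !is.na(reports$MGT)
  expect_true(any(defined))
  expect_equal(reports$MGR[defined] * reports$MGT[defined],
               rep(1, sum(defined)), tolerance = 1e-12)
})

test_that("GP is invariant to scoring-grid refinement preserving final counts", {
  coarse <- make_course(c(48, 96), c(12, 30))
  fine <- make_course(c(24, 48, 72, 96), c(5, 12, 20, 30))
  expect_equal(compute_index_report(coarse)$GP,
               compute_index_report(fine)$GP)
})

test_that("GE and GRI are additive over disjoint day partitions", {
  inc <- c(3, 7, 2, 5)
  days <- 1:4
  ge_full <- germination_energy(cumsum(inc), days)
  ge_parts <- germination_energy(cumsum(inc[1:2]), days[1:2]) +
    germination_energy(cumsum(inc[3:4]), days[3:4])
  expect_equal(ge_full, ge_parts)

  pct <- 100 * inc / 40
  expect_equal(germination_rate_index(pct, days),
               germination_rate_index(pct[1:2], days[1:2]) +
                 germination_rate_index(pct[3:4], days[3:4]))
})

test_that("treatment averaging and pooling modes both produce reports", {
  grid <- simulate_experiment(simulation_config(seed = 9))
  per_rep <- compute_indices(grid, average = FALSE)
  avg <- compute_indices(grid, average = TRUE)
  pooled <- compute_indices(grid, pool = TRUE)
  expect_equal(nrow(per_rep), 60)  # 5 T x 4 psi x 3 reps
  expect_equal(nrow(avg), 20)
  expect_equal(nrow(pooled), 20)
  # averaged GP equals the mean of replicate GPs for one treatment
  cell <- per_rep$temperature_C == 30 & per_rep$psi_MPa == 0
  expect_equal(avg$GP[avg$temperature_C == 30 & avg$psi_MPa == 0],
               mean(per_rep$GP[cell]))
})

test_that("vigor indices appear only when traits are supplied", {
  grid <- simulate_experiment(simulation_config(seed = 13))
  traits <- simulate_seedling_traits(grid, cv = 0, seed = 13)
  course <- time_courses(grid)[["30.0.1"]]
  tr <- traits[traits$temperature_C == 30 & traits$psi_MPa == 0 &
                 traits$replicate == 1, ]
  without <- compute_index_report(course)
  with_tr <- compute_index_report(course, tr)
  expect_true(all(is.na(without[c("SVI1", "SVI2", "RSR")])))
  expect_equal(with_tr$SVI1, tr$seedling_length_cm * with_tr$GP)
  expect_equal(with_tr$SVI2, tr$seed_dw_mg * with_tr$GP)
  expect_equal(with_tr$RSR, tr$root_dw_mg / tr$shoot_dw_mg)
})
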