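test_that("Gompertz hazards evaluate and integrate in closed form", {
  g <- gompertz_hazard(-9.72, 0.1)
  expect_equal(hazard_at(g, 0), exp(-9.72))
  # log-linearity: rates 10 years apart differ by a factor exp(1)
  expect_equal(hazard_at(g, 70) / hazard_at(g, 60), exp(1))

  expect_equal(cumulative_hazard(constant_hazard(0.1), 50, 60), 1.0)
  expect_equal(cumulative_hazard(g, 63.2, 63.2), 0)

  # closed form agrees with adaptive quadrature on random intervals
  set.seed(41)
  a0 <- runif(100, 0, 100)
  a1 <- a0 + runif(100, 0, 10)
  quad <- cumulative_hazard(function(a) exp(-9.72 + 0.1 * a), a0, a1)
  expect_equal(cumulative_hazard(g, a0, a1), quad, tolerance = 1e-8)

  # the calibration identity behind the 70.53-year median death age
  expect_equal(cumulative_hazard(function(a) exp(-9.7215 + 0.1 * a), 0, 70.53),
               log(2), tolerance = 1e-3)

  expect_error(hazard_at(g, 120), "0, 110")
  expect_error(cumulative_hazard(g, 50, 40), ">=")
})

test_that("cumulative hazard is additive over adjacent intervals", {
  set.seed(7)
  hs <- list(gompertz_hazard(-10.4, 0.1),
             incidence_curve(30, -6.6, 0.038),
             hazard_sum(gompertz_hazard(-10.4, 0.1),
                        incidence_curve(30, -6.6, 0.038)))
  for (h in hs) {
    a0 <- runif(50, 0, 100)
    a2 <- a0 + runif(50, 0, 10)
    a1 <- a0 + (a2 - a0) * runif(50)
    expect_equal(cumulative_hazard(h, a0, a1) + cumulative_hazard(h, a1, a2),
                 cumulative_hazard(h, a0, a2), tolerance = 1e-9)
  }
})

test_that("incidence curves vanish below their onset age", {
  inc <- incidence_curve(30, -6.6, 0.038)
  expect_identical(hazard_at(inc, 20), 0)
  expect_identical(cumulative_hazard(inc, 0, 30), 0)
  expect_gt(hazard_at(inc, 45), 0)
  # integrating across the onset only accumulates mass above it
  expect_equal(cumulative_hazard(inc, 10, 50),
               cumulative_hazard(inc, 30, 50))
})

test_that("true MRR functions reproduce the printed setting values", {
  high <- default_rates("high")
  expect_equal(round(mrr_value(high$mrr, c(40, 60, 80)), 2),
               c(3.32, 2.23, 1.49))
  low <- default_rates("low")
  expect_equal(round(mrr_value(low$mrr, c(40, 60, 80)), 2),
               c(3.79, 2.39, 1.51))
  # strictly decreasing in age when decay > 0; identically 1 when flat
  ages <- seq(0, 110, by = 5)
  expect_true(all(diff(mrr_value(high$mrr, ages)) < 0))
  expect_equal(mrr_value(loglinear_mrr(0, 0), ages), rep(1, length(ages)))
})

test_that("calibrate_m0 solves its defining median-age equation", {
  m0 <- calibrate_m0(70.53, slope_fixed = 0.1)
  expect_equal(cumulative_hazard(m0, 0, 70.53), log(2), tolerance = 1e-12)
  expect_equal(m0$log_level, -9.7215, tolerance = 1e-4)
  # a later median death age requires a lower mortality level
  expect_lt(calibrate_m0(74.00, 0.1)$log_level, m0$log_level)
})

test_that("lifetime risk matches calibration targets and a simulation oracle", {
  no_disease <- rate_set(gompertz_hazard(-10, 0.1), loglinear_mrr(0, 0),
                         incidence_curve(30, -Inf, 0))
  expect_equal(lifetime_risk(no_disease), 0)

  high <- default_rates("high")
  expect_equal(lifetime_risk(high), 0.40019, tolerance = 1e-4 / 0.40019)

  # monotone nondecreasing under pointwise increase of the incidence
  bumped <- rate_set(high$m0, high$mrr,
                     incidence_curve(30, high$incidence$log_level + 0.3,
                                     high$incidence$slope))
  expect_gt(lifetime_risk(bumped), lifetime_risk(high))

  # simulation oracle: diagnosed fraction of the full cohort within 3 SE
  pop <- high_population()
  p <- lifetime_risk(high)
  se <- sqrt(p * (1 - p) / nrow(pop))
  expect_lt(abs(mean(!is.na(pop$age_diagnosis)) - p), 3 * se)
})

test_that("incidence calibration hits lifetime risk and median onset", {
  high <- default_rates("high")
  tg <- calibration_targets(0.40019, 60.75, 74.00)
  inc <- calibrate_incidence(tg, high$m0, onset_age = 30)
  achieved <- lifetime_risk(rate_set(high$m0, high$mrr, inc))
  expect_equal(achieved, 0.40019, tolerance = 1e-4 / 0.40019)
  # frozen defaults are the calibration output
  expect_equal(inc$log_level, high$incidence$log_level, tolerance = 1e-6)
  expect_equal(inc$slope, high$incidence$slope, tolerance = 1e-6)

  # vanishing target risk gives a vanishing incidence curve
  inc0 <- calibrate_incidence(calibration_targets(0, 32.55, 70.53),
                              default_rates("low")$m0, onset_age = 18)
  expect_identical(hazard_at(inc0, 50), 0)

  # analytic median of the onset-age distribution among the diagnosed
  low <- default_rates("low")
  risk <- lifetime_risk(low)
  med_analytic <- uniroot(function(a) lifetime_risk(low, upto = a) / risk - 0.5,
                          c(18.01, 109), tol = 1e-9)$root
  expect_equal(med_analytic, 32.55, tolerance = 1e-6)

  # simulation oracle: empirical median onset within 3 SE of the target,
  # with the median's SE taken from the analytic onset density
  big <- simulate_population(low, n = 1000000L, seed = 4242)
  onsets <- big$age_diagnosis[!is.na(big$age_diagnosis)]
  dens <- (lifetime_risk(low, upto = 32.55 + 0.5) -
             lifetime_risk(low, upto = 32.55 - 0.5)) / risk
  se_med <- 1 / (2 * dens * sqrt(length(onsets)))
  expect_lt(abs(median(onsets) - 32.55), 3 * se_med)
})

test_that("rate sets expose m1 = m0 * MRR and serialise losslessly", {
  high <- default_rates("high")
  m1 <- disease_mortality(high)
  ages <- c(0, 35, 60.5, 92)
  expect_equal(hazard_at(m1, ages),
               hazard_at(high$m0, ages) * mrr_value(high$mrr, ages))
  expect_true(all(hazard_at(m1, ages) > hazard_at(high$m0, ages)))

  path <- withr::local_tempfile(fileext = ".yaml")
  write_rates_config(high, path)
  back <- read_rates_config(path)
  expect_identical(back$m0$log_level, high$m0$log_level)
  expect_identical(back$incidence$slope, high$incidence$slope)
  expect_identical(back$setting_label, "high")

  expect_error(default_rates("medium"), "high.*low")
})
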