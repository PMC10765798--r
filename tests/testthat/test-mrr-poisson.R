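test_that("person-time splitting follows the time-split classification", {
  # disease-free life dying at 75: 35 nondiseased PY, event in band [75, 76)
  pt <- split_person_time(tibble::tibble(age_diagnosis = NA_real_,
                                         age_death = 75))
  nd <- pt[pt$group == "nondiseased", ]
  expect_equal(sum(nd$person_years), 35)
  expect_equal(sum(pt$person_years[pt$group == "diseased"]), 0)
  expect_identical(nd$events[nd$band_start == 75], 1L)
  expect_identical(sum(pt$events), 1L)

  # diagnosis 60, death 70: 20 + 10 person-years, death in diseased group
  life <- tibble::tibble(age_diagnosis = 60, age_death = 70,
                         age_survey = 50)
  pt <- split_person_time(apply_micdad(life))
  expect_equal(sum(pt$person_years[pt$group == "nondiseased"]), 20)
  expect_equal(sum(pt$person_years[pt$group == "diseased"]), 10)
  expect_identical(pt$events[pt$group == "diseased" & pt$band_start == 70], 1L)

  # masked (survey at 50): the whole 30 years and the death count as healthy
  pt_obs <- split_person_time(apply_micdad(life), use_observed = TRUE)
  expect_equal(sum(pt_obs$person_years[pt_obs$group == "nondiseased"]), 30)
  expect_equal(sum(pt_obs$person_years[pt_obs$group == "diseased"]), 0)
  expect_identical(
    pt_obs$events[pt_obs$group == "nondiseased" & pt_obs$band_start == 70], 1L)

  # deaths at or past the window edge are censored, not counted
  pt80 <- split_person_time(tibble::tibble(age_diagnosis = NA_real_,
                                           age_death = 85))
  expect_identical(sum(pt80$events), 0L)
  expect_equal(sum(pt80$person_years), 40)

  expect_error(split_person_time(life, window = c(40, 80), band_width = 3),
               "divide")
})

test_that("masking reallocates person-time but never creates or destroys it", {
  pop <- high_population()[1:20000, ]
  pt_true <- split_person_time(pop, use_observed = FALSE)
  pt_obs <- split_person_time(pop, use_observed = TRUE)
  expect_equal(sum(pt_true$person_years), sum(pt_obs$person_years))
  expect_identical(sum(pt_true$events), sum(pt_obs$events))

  # band-wise, the nondiseased group can only gain under masking
  nd_true <- pt_true[pt_true$group == "nondiseased", ]
  nd_obs <- pt_obs[pt_obs$group == "nondiseased", ]
  expect_true(all(nd_obs$person_years - nd_true$person_years > -1e-9))
  expect_true(all(nd_obs$events >= nd_true$events))

  # no exposure, no events
  expect_true(all(pt_true$events[pt_true$person_years == 0] == 0))
})

test_that("the Poisson fit matches closed forms and independent oracles", {
  # saturated two-band table has a closed-form solution
  cells <- tibble::tibble(group = "g", band_start = c(49.5, 69.5),
                          events = c(2L, 8L), person_years = c(100, 100))
  fit <- fit_poisson_loglinear(cells)
  expect_true(fit$converged)
  expect_equal(fit$coef[["slope"]], log(4) / 20, tolerance = 1e-9)
  expect_equal(fit$coef[["intercept"]], log(0.02) - 50 * log(4) / 20,
               tolerance = 1e-9)

  # single informative band collapses to the event rate with zero slope
  one <- tibble::tibble(band_start = 60, events = 5L, person_years = 100)
  fit1 <- fit_poisson_loglinear(one)
  expect_equal(rate_at(fit1, 60), 0.05)
  expect_identical(fit1$coef[["slope"]], 0)

  expect_error(fit_poisson_loglinear(
    tibble::tibble(band_start = 40:44, events = 0L, person_years = 10)),
    "no events")

  # Newton-Raphson against a brute-force likelihood grid search
  set.seed(12)
  for (rep in 1:4) {
    tab <- tibble::tibble(
      band_start = seq(40, 75, by = 5),
      events = rpois(8, lambda = 3),
      person_years = runif(8, 50, 150))
    if (sum(tab$events) == 0) next
    fit <- fit_poisson_loglinear(tab, band_width = 5)
    grid <- grid_poisson_fit(tab, band_width = 5)
    expect_equal(unname(fit$coef), grid, tolerance = 1e-4)
    # and against the standard IRLS fit with person-years offset
    glm_fit <- glm(events ~ I(band_start + 2.5) + offset(log(person_years)),
                   family = poisson(), data = tab)
    expect_equal(unname(fit$coef), unname(coef(glm_fit)), tolerance = 1e-6)
  }
})

test_that("rates simulated from Gompertz hazards are recovered", {
  pop <- high_population()
  cells <- split_person_time(pop, use_observed = FALSE)
  fit_n <- fit_poisson_loglinear(cells[cells$group == "nondiseased", ])
  fit_d <- fit_poisson_loglinear(cells[cells$group == "diseased", ])
  td <- tidy(fit_n)
  # nondiseased person-time is exposed to m0: slope 0.1 within 3 SE
  expect_lt(abs(td$estimate[td$term == "slope"] - 0.1),
            3 * td$std.error[td$term == "slope"])
  # diseased mortality has slope 0.1 - 0.02
  td_d <- tidy(fit_d)
  expect_lt(abs(td_d$estimate[td_d$term == "slope"] - 0.08),
            3 * td_d$std.error[td_d$term == "slope"])
  expect_true(all(glance(fit_n)$converged, glance(fit_d)$converged))
})

test_that("MRR curves evaluate the fitted log-linear ratio", {
  cells <- tibble::tibble(band_start = c(49.5, 69.5), events = c(4L, 9L),
                          person_years = c(80, 120))
  fit <- fit_poisson_loglinear(cells)
  expect_equal(mrr_curve(fit, fit, c(40, 60, 80))$mrr, rep(1, 3))

  f1 <- fit
  f2 <- fit
  f2$coef <- fit$coef + c(2, -0.02) # diseased fit offset by the true ratio
  expect_equal(mrr_curve(f2, f1, 60)$mrr, exp(0.8))
  expect_equal(round(mrr_curve(f2, f1, 40)$mrr, 2), 3.32)

  bad <- fit
  bad$converged <- FALSE
  expect_error(mrr_curve(bad, fit), "converged")
})

test_that("estimation without masking recovers the true input MRR", {
  pop <- high_population()
  est <- estimate_mrr(pop, ages = c(40, 60, 80), use_observed = FALSE)
  truth <- mrr_value(default_rates("high")$mrr, est$age)
  # correct specification: log MRR within 3 delta-method SE at each age
  expect_true(all(abs(log(est$mrr) - log(truth)) < 3 * est$log_se))
})
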