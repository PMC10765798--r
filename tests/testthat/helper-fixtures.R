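# Shared simulation fixtures, built once per test run and cached so the
# expensive full-scale populations and studies are reused across test files.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = fixture_env, inherits = FALSE)) {
    assign(name, make(), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

# Full-scale high-incidence population (100 000 lives) with survey ages and
# masking applied; the seeds are arbitrary fixed constants.
high_population <- function() fixture("high_pop", function() {
  pop <- simulate_population(default_rates("high"), n = 100000L, seed = 101)
  apply_micdad(assign_survey_ages(pop, seed = 202))
})

high_study <- function() fixture("high_study", function() {
  run_study(high_population(), study_config(seed = 303))
})

low_population <- function() fixture("low_pop", function() {
  pop <- simulate_population(default_rates("low"), n = 100000L, seed = 111)
  apply_micdad(assign_survey_ages(pop, seed = 222))
})

low_study <- function() fixture("low_study", function() {
  run_study(low_population(), study_config(seed = 333))
})

# Brute-force Poisson likelihood maximiser: iteratively refined grid search,
# independent of the Newton-Raphson implementation under test.
grid_poisson_fit <- function(cells, band_width = 1) {
  keep <- cells$person_years > 0
  d <- cells$events[keep]
  y <- cells$person_years[keep]
  a <- cells$band_start[keep] + band_width / 2
  ll <- function(b0, b1) sum(d * (b0 + b1 * a + log(y))) -
    sum(exp(b0 + b1 * a) * y)
  centre <- c(log(sum(d) / sum(y)), 0)
  half <- c(10, 0.5)
  for (round in 1:8) {
    b0s <- seq(centre[1] - half[1], centre[1] + half[1], length.out = 41)
    b1s <- seq(centre[2] - half[2], centre[2] + half[2], length.out = 41)
    vals <- outer(b0s, b1s, Vectorize(ll))
    best <- arrayInd(which.max(vals), dim(vals))
    centre <- c(b0s[best[1]], b1s[best[2]])
    half <- half * 0.12
  }
  centre
}
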