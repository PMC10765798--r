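#' Draw event ages by inverting the cumulative hazard
#'
#' Solves \eqn{\Lambda(\mathrm{start}, a^*) = -\log u} for the event age
#' \eqn{a^*}, the inverse-cumulative-hazard method for event-time sampling.
#' If even the total hazard up to the 110-year age cap is smaller than
#' \eqn{-\log u}, the draw is cap-censored and `Inf` is returned. The root is
#' located by monotone bisection on the closed-form cumulative hazard to an
#' absolute tolerance of 1e-8 years; the call is vectorised over
#' `start_age` and `u`.
#'
#' @param hazard An `idm_hazard`.
#' @param start_age Age(s) at which the clock starts, in \[0, 110).
#' @param u Uniform(0, 1) draw(s).
#' @return Event ages in years; `Inf` marks a draw censored at the age cap.
#' @export
sample_event_age <- function(hazard, start_age, u) {
  check_age(start_age, "start_age")
  if (!is.numeric(u) || anyNA(u) || any(u <= 0) || any(u >= 1)) {
    stop("`u` must lie strictly in (0, 1)", call. = FALSE)
  }
  n <- max(length(start_age), length(u))
  start_age <- rep_len(start_age, n)
  u <- rep_len(u, n)
  target <- -log(u)
  lo <- start_age
  hi <- rep(AGE_MAX, n)
  censored <- cumulative_hazard(hazard, start_age, hi) < target
  # 50 bisection steps shrink the bracket below 1e-13 years
  for (k in 1:50) {
    mid <- (lo + hi) / 2
    below <- cumulative_hazard(hazard, start_age, mid) < target
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  out <- (lo + hi) / 2
  out[censored] <- Inf
  out
}

#' Simulation configuration for a birth cohort
#'
#' @param n_individuals Cohort size (default 100 000).
#' @param seed Integer seed for the population's random-number stream.
#' @param age_cap Upper age bound in years; individuals with no event drawn
#'   by this age are assigned death at the cap (default 110).
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_individuals = 100000L, seed = 1L, age_cap = AGE_MAX) {
  stopifnot(n_individuals >= 0, age_cap == AGE_MAX,
            is.numeric(seed), length(seed) == 1L)
  structure(list(n_individuals = as.integer(n_individuals),
                 seed = as.integer(seed), age_cap = age_cap),
            class = "sim_config")
}

#' Simulate a birth cohort through the illness-death model
#'
#' Discrete-event microsimulation: each individual starts healthy at age 0.
#' The age of the first transition is drawn from the combined
#' leaving-healthy hazard \eqn{m_0(a) + i(a)}; at the realised age the event
#' is a diagnosis with probability \eqn{i(a^*)/(i(a^*) + m_0(a^*))} and a
#' death otherwise. Diagnosed individuals then draw their death age from the
#' diseased mortality \eqn{m_1(a) = m_0(a)\,\mathrm{MRR}(a)} starting at the
#' diagnosis age. Draws censored at the 110-year cap are assigned death at
#' exactly 110, so every life course ends in the death state.
#'
#' @param rates A [rate_set()].
#' @param config A [sim_config()], or `NULL` to build one from `n` and `seed`.
#' @param n,seed Shortcuts used when `config` is `NULL`.
#' @return A tibble with one row per individual: `id`, `age_diagnosis`
#'   (`NA` for those disease-free at death), `age_death`. Deterministic for a
#'   fixed seed.
#' @examples
#' pop <- simulate_population(default_rates("high"), n = 1000, seed = 7)
#' mean(!is.na(pop$age_diagnosis)) # about 0.40 lifetime diagnosis risk
#' @export
simulate_population <- function(rates, config = NULL, n = 100000L, seed = 1L) {
  stopifnot(inherits(rates, "rate_set"))
  if (is.null(config)) config <- sim_config(n_individuals = n, seed = seed)
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  if (n == 0L) {
    return(tibble::tibble(id = integer(), age_diagnosis = double(),
                          age_death = double()))
  }
  withr_seed <- local_rng_seed(config$seed)
  on.exit(withr_seed(), add = TRUE)

  total <- hazard_sum(rates$m0, rates$incidence)
  u1 <- stats::runif(n)
  first <- sample_event_age(total, rep(0, n), u1)
  capped <- !is.finite(first)
  a1 <- ifelse(capped, AGE_MAX, first)

  # event-type decision at the realised age: thinning-equivalent split of the
  # combined hazard into its competing components
  i_at <- hazard_at(rates$incidence, a1)
  m0_at <- hazard_at(rates$m0, a1)
  p_disease <- ifelse(capped, 0, i_at / (i_at + m0_at))
  diseased <- stats::runif(n) < p_disease

  age_diagnosis <- rep(NA_real_, n)
  age_death <- a1
  if (any(diseased)) {
    m1 <- disease_mortality(rates)
    a2 <- sample_event_age(m1, a1[diseased], stats::runif(sum(diseased)))
    age_diagnosis[diseased] <- a1[diseased]
    age_death[diseased] <- ifelse(is.finite(a2), a2, AGE_MAX)
  }
  tibble::tibble(id = seq_len(n), age_diagnosis = age_diagnosis,
                 age_death = age_death)
}

#' @rdname simulate_population
#' @export
simulate_life <- function(rates, seed = 1L) {
  simulate_population(rates, n = 1L, seed = seed)
}

# Seed the session RNG reproducibly and restore the previous state on exit.
local_rng_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

# Derive distinct sub-stream seeds (below 2^31) from one top-level seed, so
# pipeline stages (simulation, survey, sampling) can be re-run independently.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(simulation = 101L, survey = 211L, sampling = 307L)
  if (!stream %in% names(offsets)) stop("unknown seed stream: ", stream)
  as.integer((as.double(seed) * 7919 + offsets[[stream]]) %% 2147483647)
}

#' Count transitions in a simulated population
#'
#' Tabulates the three possible transitions of the illness-death model.
#' Conservation holds by construction: healthy-to-disease plus
#' healthy-to-death equals the cohort size, and every diagnosed individual
#' later dies diseased (chronic disease, no remission).
#'
#' @param population A tibble from [simulate_population()].
#' @return A one-row tibble with columns `healthy_to_disease`,
#'   `healthy_to_death`, `disease_to_death`.
#' @export
transition_counts <- function(population) {
  stopifnot(all(c("age_diagnosis", "age_death") %in% names(population)))
  n_dis <- sum(!is.na(population$age_diagnosis))
  tibble::tibble(
    healthy_to_disease = n_dis,
    healthy_to_death = nrow(population) - n_dis,
    disease_to_death = n_dis
  )
}

#' Convert a population to Lexis-style long format
#'
#' One row per state episode with age at entry and exit and the states
#' occupied: healthy episodes end in diagnosis (`D`) or death (`X`); disease
#' episodes always end in death.
#'
#' @param population A tibble from [simulate_population()].
#' @return A tibble with columns `id`, `age_in`, `age_out`, `state_in`
#'   (`"H"` or `"D"`), `state_out` (`"D"` or `"X"`).
#' @export
as_lexis <- function(population) {
  stopifnot(all(c("id", "age_diagnosis", "age_death") %in% names(population)))
  healthy <- tibble::tibble(
    id = population$id,
    age_in = 0,
    age_out = ifelse(is.na(population$age_diagnosis),
                     population$age_death, population$age_diagnosis),
    state_in = "H",
    state_out = ifelse(is.na(population$age_diagnosis), "X", "D")
  )
  dis <- dplyr::filter(population, !is.na(.data$age_diagnosis))
  diseased <- tibble::tibble(
    id = dis$id,
    age_in = dis$age_diagnosis,
    age_out = dis$age_death,
    state_in = "D",
    state_out = "X"
  )
  dplyr::arrange(dplyr::bind_rows(healthy, diseased), .data$id, .data$age_in)
}

#' @rdname as_lexis
#' @param lexis A Lexis-format tibble as produced by [as_lexis()].
#' @export
from_lexis <- function(lexis) {
  stopifnot(all(c("id", "age_in", "age_out", "state_in", "state_out")
                %in% names(lexis)))
  healthy <- dplyr::filter(lexis, .data$state_in == "H")
  dis_age <- ifelse(healthy$state_out == "D", healthy$age_out, NA_real_)
  death <- dplyr::summarise(dplyr::group_by(lexis, .data$id),
                            age_death = max(.data$age_out), .groups = "drop")
  out <- tibble::tibble(id = healthy$id, age_diagnosis = dis_age)
  dplyr::arrange(dplyr::left_join(out, death, by = "id"), .data$id)
}
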