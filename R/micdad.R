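#' Assign one-time survey participation ages
#'
#' Each individual participates in a cross-sectional survey exactly once, at
#' an age drawn independently from a Uniform(`lo`, `hi`) distribution
#' (default 18 to 110 years: the lower bound excludes children, the upper
#' bound guarantees every individual has died by the end of follow-up).
#'
#' @param population A tibble from [simulate_population()].
#' @param seed Integer seed for the survey-age stream.
#' @param lo,hi Bounds of the uniform survey-age distribution, `lo < hi`.
#' @return The population with an `age_survey` column appended.
#' @export
assign_survey_ages <- function(population, seed = 1L, lo = 18, hi = 110) {
  if (!(is.numeric(lo) && is.numeric(hi) && lo < hi)) {
    stop("`lo` must be smaller than `hi`", call. = FALSE)
  }
  restore <- local_rng_seed(seed)
  on.exit(restore(), add = TRUE)
  dplyr::mutate(population,
                age_survey = stats::runif(dplyr::n(), min = lo, max = hi))
}

#' Apply misclassification of disease status at death (MicDaD)
#'
#' Implements the masking rule of one-time survey participation: a diagnosis
#' is observed only if it happened at or before the survey
#' (`age_diagnosis <= age_survey`); diagnoses after study participation
#' remain undetected, so those individuals are wrongly carried as
#' disease-free at death. Death ages are never altered and diagnoses are
#' never invented. The boundary tie `age_survey == age_diagnosis` counts as
#' observed (the rule masks strictly later diagnoses); under continuous ages
#' the tie has probability zero, but fixing it keeps results reproducible.
#'
#' @param population A tibble carrying `age_diagnosis`, `age_death` and
#'   `age_survey` (see [assign_survey_ages()]), or a single-row life course
#'   with `age_survey` supplied separately.
#' @param age_survey Optional survey age(s) overriding a missing or existing
#'   `age_survey` column.
#' @return The input with columns `age_survey` and `observed_diagnosis`
#'   (`NA` where the true diagnosis is masked or absent).
#' @export
apply_micdad <- function(population, age_survey = NULL) {
  stopifnot(all(c("age_diagnosis", "age_death") %in% names(population)))
  if (!is.null(age_survey)) {
    population$age_survey <- rep_len(age_survey, nrow(population))
  }
  if (is.null(population$age_survey)) {
    stop("no `age_survey` column; call assign_survey_ages() first",
         call. = FALSE)
  }
  if (any(population$age_survey < 18 | population$age_survey > AGE_MAX)) {
    stop("`age_survey` must lie in [18, 110]", call. = FALSE)
  }
  dplyr::mutate(population,
                observed_diagnosis = dplyr::if_else(
                  !is.na(.data$age_diagnosis) &
                    .data$age_diagnosis <= .data$age_survey,
                  .data$age_diagnosis, NA_real_))
}

#' Fraction of diagnosed individuals masked by MicDaD
#'
#' Diagnostic summary: among individuals who truly entered the disease state,
#' the proportion whose diagnosis went undetected because it occurred after
#' their survey participation.
#'
#' @param surveyed_population Output of [apply_micdad()].
#' @return A proportion in \[0, 1\].
#' @export
misclassification_fraction <- function(surveyed_population) {
  stopifnot(all(c("age_diagnosis", "observed_diagnosis")
                %in% names(surveyed_population)))
  if (nrow(surveyed_population) == 0L) {
    stop("empty population", call. = FALSE)
  }
  diagnosed <- !is.na(surveyed_population$age_diagnosis)
  if (!any(diagnosed)) {
    stop("no diagnosed individuals: misclassification fraction is undefined",
         call. = FALSE)
  }
  mean(is.na(surveyed_population$observed_diagnosis[diagnosed]))
}
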