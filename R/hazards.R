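#' Age-dependent transition intensities for the illness-death model
#'
#' Constructors for the hazard functions used as transition intensities of the
#' three-state illness-death model (healthy, diseased, dead). All hazards are
#' defined on the age interval \[0, 110\] years; age is the only timescale.
#'
#' * `gompertz_hazard()` is the standard adult-mortality form
#'   \eqn{h(a) = \exp(\beta_0 + \beta_1 a)}, log-linear in age.
#' * `constant_hazard()` is an age-constant rate, mainly useful for testing
#'   and degenerate scenarios.
#' * `incidence_curve()` is a Gompertz-type rate that is identically zero
#'   below an onset age, so that no diagnoses occur in childhood.
#' * `hazard_sum()` is the sum of several hazards, e.g. the total
#'   leaving-the-healthy-state intensity \eqn{m_0(a) + i(a)} used by the
#'   competing-risk event sampler.
#'
#' @param log_level Log of the rate at age 0 (per year, log scale).
#' @param slope Per-year change of the log rate.
#' @param rate Constant per-year rate (nonnegative).
#' @param onset_age Age in years below which the incidence is exactly 0.
#' @param ... For `hazard_sum()`, hazard objects to add.
#'
#' @return An object of class `idm_hazard` that can be evaluated with
#'   [hazard_at()] and integrated with [cumulative_hazard()].
#' @seealso [loglinear_mrr()], [rate_set()], [sample_event_age()]
#' @examples
#' m0 <- gompertz_hazard(-9.72, 0.1)
#' hazard_at(m0, c(0, 40, 70))
#' cumulative_hazard(m0, 0, 70.53) # about log(2): 70.53 is the median death age
#' @export
gompertz_hazard <- function(log_level, slope) {
  stopifnot(is.numeric(log_level), length(log_level) == 1L, is.finite(log_level),
            is.numeric(slope), length(slope) == 1L, is.finite(slope))
  structure(list(log_level = log_level, slope = slope),
            class = c("gompertz_hazard", "idm_hazard"))
}

#' @rdname gompertz_hazard
#' @export
constant_hazard <- function(rate) {
  stopifnot(is.numeric(rate), length(rate) == 1L, is.finite(rate), rate >= 0)
  structure(list(rate = rate), class = c("constant_hazard", "idm_hazard"))
}

#' @rdname gompertz_hazard
#' @export
incidence_curve <- function(onset_age, log_level, slope) {
  stopifnot(is.numeric(onset_age), length(onset_age) == 1L,
            onset_age >= 0, onset_age <= 110)
  structure(list(onset_age = onset_age, log_level = log_level, slope = slope),
            class = c("incidence_curve", "idm_hazard"))
}

#' @rdname gompertz_hazard
#' @export
hazard_sum <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) >= 1L,
            all(vapply(parts, inherits, logical(1), "idm_hazard")))
  structure(list(parts = parts), class = c("hazard_sum", "idm_hazard"))
}

AGE_MAX <- 110

check_age <- function(a, arg = "age") {
  if (!is.numeric(a) || anyNA(a) || any(a < 0) || any(a > AGE_MAX)) {
    stop(sprintf("`%s` must lie in [0, %d] years", arg, AGE_MAX), call. = FALSE)
  }
  invisible(a)
}

#' Evaluate a hazard at given ages
#'
#' @param hazard An `idm_hazard` object.
#' @param age Numeric vector of ages in \[0, 110\] years.
#' @return Per-year rates, same length as `age`; nonnegative and finite.
#'   An [incidence_curve()] returns exactly 0 below its onset age.
#' @export
hazard_at <- function(hazard, age) {
  check_age(age)
  UseMethod("hazard_at")
}

#' @export
hazard_at.gompertz_hazard <- function(hazard, age) {
  exp(hazard$log_level + hazard$slope * age)
}

#' @export
hazard_at.constant_hazard <- function(hazard, age) {
  rep_len(hazard$rate, length(age))
}

#' @export
hazard_at.incidence_curve <- function(hazard, age) {
  ifelse(age < hazard$onset_age, 0,
         exp(hazard$log_level + hazard$slope * age))
}

#' @export
hazard_at.hazard_sum <- function(hazard, age) {
  Reduce(`+`, lapply(hazard$parts, hazard_at, age = age))
}

#' Cumulative hazard over an age interval
#'
#' Computes \eqn{\Lambda(a_0, a_1) = \int_{a_0}^{a_1} h(a)\,da}. Gompertz-type
#' hazards use the closed form \eqn{e^{\beta_0}(e^{\beta_1 a_1} -
#' e^{\beta_1 a_0})/\beta_1}; arbitrary hazard functions (plain R functions)
#' fall back to adaptive quadrature with relative tolerance `1e-10`.
#' The result is additive over adjacent intervals.
#'
#' @param hazard An `idm_hazard` object, or a plain vectorised function of age.
#' @param a0,a1 Interval endpoints in years, `0 <= a0 <= a1 <= 110`.
#'   Vectors are recycled to a common length.
#' @return Nonnegative dimensionless cumulative hazard.
#' @export
cumulative_hazard <- function(hazard, a0, a1) {
  check_age(a0, "a0")
  check_age(a1, "a1")
  if (any(a1 < a0)) stop("`a1` must be >= `a0`", call. = FALSE)
  UseMethod("cumulative_hazard")
}

gompertz_cum <- function(log_level, slope, a0, a1) {
  if (abs(slope) < 1e-12) {
    exp(log_level) * (a1 - a0)
  } else {
    exp(log_level) * (exp(slope * a1) - exp(slope * a0)) / slope
  }
}

#' @export
cumulative_hazard.gompertz_hazard <- function(hazard, a0, a1) {
  gompertz_cum(hazard$log_level, hazard$slope, a0, a1)
}

#' @export
cumulative_hazard.constant_hazard <- function(hazard, a0, a1) {
  hazard$rate * (a1 - a0)
}

#' @export
cumulative_hazard.incidence_curve <- function(hazard, a0, a1) {
  lo <- pmax(a0, hazard$onset_age)
  hi <- pmax(a1, hazard$onset_age)
  gompertz_cum(hazard$log_level, hazard$slope, lo, hi)
}

#' @export
cumulative_hazard.hazard_sum <- function(hazard, a0, a1) {
  Reduce(`+`, lapply(hazard$parts, cumulative_hazard, a0 = a0, a1 = a1))
}

#' @export
cumulative_hazard.function <- function(hazard, a0, a1) {
  n <- max(length(a0), length(a1))
  a0 <- rep_len(a0, n)
  a1 <- rep_len(a1, n)
  vapply(seq_len(n), function(i) {
    if (a1[i] == a0[i]) return(0)
    stats::integrate(hazard, a0[i], a1[i], rel.tol = 1e-10,
                     subdivisions = 500L)$value
  }, numeric(1))
}

#' @export
print.idm_hazard <- function(x, ...) {
  cat("<", class(x)[1], ">\n", sep = "")
  fields <- x[!vapply(x, is.list, logical(1))]
  for (nm in names(fields)) cat("  ", nm, ": ", format(fields[[nm]]), "\n", sep = "")
  invisible(x)
}

#' Log-linear mortality rate ratio
#'
#' The true, age-dependent mortality rate ratio of diseased versus
#' non-diseased individuals, \eqn{\mathrm{MRR}(a) = \exp(\beta_0 - \beta_1 a)}.
#' The log-linear form is implied by the settings shipped with the package,
#' whose true ratios decline geometrically in 20-year age steps.
#'
#' @param intercept Log ratio at age 0.
#' @param decay Per-year decrease of the log ratio (positive values give an
#'   MRR that falls towards 1 with age).
#' @return An object of class `loglinear_mrr`.
#' @examples
#' mrr_value(loglinear_mrr(2, 0.02), c(40, 60, 80)) # 3.32, 2.23, 1.49
#' @export
loglinear_mrr <- function(intercept, decay) {
  stopifnot(is.numeric(intercept), length(intercept) == 1L, is.finite(intercept),
            is.numeric(decay), length(decay) == 1L, is.finite(decay))
  structure(list(intercept = intercept, decay = decay), class = "loglinear_mrr")
}

#' Evaluate a mortality rate ratio at given ages
#'
#' @param ratio A [loglinear_mrr()] object.
#' @param age Ages in \[0, 110\] years.
#' @return Positive ratios `exp(intercept - decay * age)`.
#' @export
mrr_value <- function(ratio, age) {
  stopifnot(inherits(ratio, "loglinear_mrr"))
  check_age(age)
  exp(ratio$intercept - ratio$decay * age)
}

#' @export
print.loglinear_mrr <- function(x, ...) {
  cat("<loglinear_mrr> exp(", format(x$intercept), " - ",
      format(x$decay), " * age)\n", sep = "")
  invisible(x)
}

#' Bundle of illness-death model transition intensities
#'
#' A `rate_set` holds the three transition intensities of the illness-death
#' model: mortality of the non-diseased `m0(a)`, incidence `i(a)`, and -- via
#' the true rate ratio -- mortality of the diseased
#' `m1(a) = m0(a) * MRR(a)`.
#'
#' @param m0 A [gompertz_hazard()]: mortality rate of the non-diseased.
#' @param mrr A [loglinear_mrr()]: true diseased/non-diseased rate ratio.
#' @param incidence An [incidence_curve()]: healthy-to-diseased rate.
#' @param setting_label Optional label, `"high"`, `"low"` or `"custom"`.
#' @return An object of class `rate_set`.
#' @seealso [default_rates()] for the two shipped disease settings.
#' @export
rate_set <- function(m0, mrr, incidence, setting_label = "custom") {
  stopifnot(inherits(m0, "gompertz_hazard"),
            inherits(mrr, "loglinear_mrr"),
            inherits(incidence, "incidence_curve"),
            is.character(setting_label), length(setting_label) == 1L)
  structure(list(m0 = m0, mrr = mrr, incidence = incidence,
                 setting_label = setting_label),
            class = "rate_set")
}

#' Mortality hazard of the diseased implied by a rate set
#'
#' Since `m0` is Gompertz and the MRR is log-linear, the diseased mortality
#' `m1(a) = m0(a) * MRR(a)` is again Gompertz with level
#' `log_level + intercept` and slope `slope - decay`.
#'
#' @param rates A [rate_set()].
#' @return A [gompertz_hazard()] for `m1`.
#' @export
disease_mortality <- function(rates) {
  stopifnot(inherits(rates, "rate_set"))
  gompertz_hazard(rates$m0$log_level + rates$mrr$intercept,
                  rates$m0$slope - rates$mrr$decay)
}

#' @export
print.rate_set <- function(x, ...) {
  cat("<rate_set> setting:", x$setting_label, "\n")
  cat(" m0: Gompertz(log_level = ", format(x$m0$log_level),
      ", slope = ", format(x$m0$slope), ")\n", sep = "")
  cat(" mrr: exp(", format(x$mrr$intercept), " - ",
      format(x$mrr$decay), " * age)\n", sep = "")
  cat(" incidence: onset ", format(x$incidence$onset_age),
      " y, Gompertz(log_level = ", format(x$incidence$log_level),
      ", slope = ", format(x$incidence$slope), ")\n", sep = "")
  invisible(x)
}
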