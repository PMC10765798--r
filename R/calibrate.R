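#' Calibration targets for a disease setting
#'
#' The printed summary quantities that the shipped rate sets are calibrated
#' against: the lifetime risk of diagnosis, the median age at diagnosis among
#' the diagnosed, and the median age at death among individuals dying
#' non-diseased.
#'
#' @param lifetime_risk Probability of ever entering the disease state,
#'   in (0, 1).
#' @param median_onset Median age at diagnosis (years), among the diagnosed.
#' @param median_death_nondiseased Median age at death (years) among those
#'   dying without a diagnosis.
#' @return A `calibration_targets` object.
#' @export
calibration_targets <- function(lifetime_risk, median_onset,
                                median_death_nondiseased) {
  stopifnot(lifetime_risk >= 0, lifetime_risk <= 1,
            median_onset > 0, median_onset < median_death_nondiseased,
            median_death_nondiseased <= AGE_MAX)
  structure(list(lifetime_risk = lifetime_risk,
                 median_onset = median_onset,
                 median_death_nondiseased = median_death_nondiseased),
            class = "calibration_targets")
}

#' Lifetime risk of diagnosis under competing mortality
#'
#' The probability of ever entering the disease state,
#' \deqn{\int_0^{110} i(a) \exp(-\Lambda_i(0,a) - \Lambda_{m_0}(0,a))\,da,}
#' i.e. the chance that disease onset wins the competing risk against death
#' while healthy. Computed via integration by parts,
#' \deqn{S_{m_0}(c) - S_i(u)S_{m_0}(u) - \int_c^{u} S_i(a)\, m_0(a)
#' S_{m_0}(a)\, da,}
#' whose integrand is bounded by \eqn{m_0}, so adaptive quadrature stays
#' accurate even when the incidence level is extreme (as happens transiently
#' during calibration root searches).
#'
#' @param rates A [rate_set()].
#' @param upto Upper age of the integral (default 110); lower values give the
#'   probability of diagnosis before that age.
#' @return Probability in \[0, 1\].
#' @export
lifetime_risk <- function(rates, upto = AGE_MAX) {
  stopifnot(inherits(rates, "rate_set"))
  check_age(upto, "upto")
  inc <- rates$incidence
  m0 <- rates$m0
  onset <- inc$onset_age
  if (upto <= onset) return(0)
  surv_i <- function(a) exp(-cumulative_hazard(inc, rep(0, length(a)), a))
  surv_m0 <- function(a) exp(-cumulative_hazard(m0, rep(0, length(a)), a))
  integrand <- function(a) surv_i(a) * hazard_at(m0, a) * surv_m0(a)
  val <- surv_m0(onset) - surv_i(upto) * surv_m0(upto) -
    stats::integrate(integrand, onset, upto, rel.tol = 1e-10,
                     subdivisions = 1000L)$value
  min(max(val, 0), 1)
}

# CDF value (unnormalised mass) of the death-age distribution of individuals
# dying non-diseased: int_0^m m0(a) S_m0(a) S_i(a) da
nondiseased_death_mass <- function(rates, m) {
  integrand <- function(a) {
    hazard_at(rates$m0, a) *
      exp(-cumulative_hazard(rates$m0, rep(0, length(a)), a) -
            cumulative_hazard(rates$incidence, rep(0, length(a)), a))
  }
  stats::integrate(integrand, 0, m, rel.tol = 1e-10, subdivisions = 1000L)$value
}

#' Calibrate the non-diseased mortality level to a median death age
#'
#' Solves the Gompertz level in closed form so that the cumulative hazard of
#' the `m0`-only process from birth to the target age equals `log(2)`, making
#' that age the median of the death-age distribution when no competing
#' diagnosis is present. The slope is held fixed (one target, one free
#' parameter).
#'
#' @param target_median_death Target median age at death in years, in
#'   (40, 110).
#' @param slope_fixed Gompertz slope per year (default 0.1, a typical adult
#'   value).
#' @return A [gompertz_hazard()].
#' @examples
#' calibrate_m0(70.53)$log_level # about -9.72
#' @export
calibrate_m0 <- function(target_median_death, slope_fixed = 0.1) {
  stopifnot(target_median_death > 40, target_median_death < AGE_MAX,
            slope_fixed > 0)
  log_level <- log(log(2) * slope_fixed /
                     (exp(slope_fixed * target_median_death) - 1))
  gompertz_hazard(log_level, slope_fixed)
}

#' Calibrate the incidence curve to lifetime risk and median onset
#'
#' Two-parameter root find: given the non-diseased mortality `m0` and an onset
#' age, the Gompertz level and slope of the incidence curve are solved so that
#' (a) the competing-risk lifetime risk of diagnosis equals
#' `targets$lifetime_risk` and (b) the median of the onset-age distribution
#' among the diagnosed equals `targets$median_onset`. The solver nests a
#' monotone 1-d root find for the level (given a slope) inside a 1-d root find
#' for the slope; both to relative tolerance 1e-6 or better.
#'
#' @param targets A [calibration_targets()] (the median death entry is unused
#'   here).
#' @param m0 The calibrated [gompertz_hazard()] for non-diseased mortality.
#' @param onset_age Age below which incidence is 0.
#' @return An [incidence_curve()].
#' @export
calibrate_incidence <- function(targets, m0, onset_age) {
  stopifnot(inherits(targets, "calibration_targets"),
            inherits(m0, "gompertz_hazard"))
  risk <- targets$lifetime_risk
  med <- targets$median_onset
  if (risk <= 0) return(incidence_curve(onset_age, -Inf, 0))
  stopifnot(risk < 1, med > onset_age, med < AGE_MAX)

  risk_at <- function(log_level, slope, upto = AGE_MAX) {
    lifetime_risk(rate_set(m0, loglinear_mrr(0, 0),
                           incidence_curve(onset_age, log_level, slope)),
                  upto = upto)
  }
  level_for <- function(slope) {
    stats::uniroot(function(b0) risk_at(b0, slope) - risk,
                   lower = -60, upper = 45, tol = 1e-12)$root
  }
  median_gap <- function(slope) {
    b0 <- level_for(slope)
    m <- stats::uniroot(function(a) risk_at(b0, slope, upto = a) / risk - 0.5,
                        lower = onset_age + 1e-6, upper = AGE_MAX - 0.1,
                        tol = 1e-9)$root
    m - med
  }
  slope <- tryCatch(
    stats::uniroot(median_gap, lower = -0.3, upper = 0.3, tol = 1e-10)$root,
    error = function(e) {
      stop("incidence calibration did not converge: ", conditionMessage(e),
           call. = FALSE)
    })
  out <- incidence_curve(onset_age, level_for(slope), slope)
  achieved <- risk_at(out$log_level, out$slope)
  if (abs(achieved - risk) > 1e-6 * max(risk, 1e-12)) {
    stop(sprintf("incidence calibration residual too large: %.3g", achieved - risk),
         call. = FALSE)
  }
  out
}

#' Calibrate a complete rate set for a disease setting
#'
#' Alternates [calibrate_incidence()] with a re-solve of the `m0` level until
#' the median age at death *among individuals dying non-diseased* matches the
#' target. That median is what population summaries report, and in a
#' high-incidence setting it differs appreciably from the median of the
#' `m0`-only process because diagnosis competes with death: individuals who
#' die non-diseased are selectively those who died before onset could occur.
#' The fixed point typically converges in a handful of iterations.
#'
#' @param targets A [calibration_targets()].
#' @param mrr A [loglinear_mrr()] giving the true rate ratio (held fixed).
#' @param onset_age Incidence onset age in years.
#' @param slope_fixed Gompertz slope of `m0` (default 0.1).
#' @param setting_label Label stored on the result.
#' @param tol Convergence tolerance on the `m0` log level.
#' @return A calibrated [rate_set()].
#' @export
calibrate_rate_set <- function(targets, mrr, onset_age, slope_fixed = 0.1,
                               setting_label = "custom", tol = 1e-9) {
  stopifnot(inherits(targets, "calibration_targets"))
  m0 <- calibrate_m0(targets$median_death_nondiseased, slope_fixed)
  med_target <- targets$median_death_nondiseased
  for (iter in 1:40) {
    inc <- calibrate_incidence(targets, m0, onset_age)
    rs <- function(l) rate_set(gompertz_hazard(l, slope_fixed), mrr, inc)
    nd_median_gap <- function(l) {
      r <- rs(l)
      mass <- nondiseased_death_mass(r, AGE_MAX)
      m <- stats::uniroot(function(a) nondiseased_death_mass(r, a) / mass - 0.5,
                          lower = 1, upper = AGE_MAX, tol = 1e-9)$root
      m - med_target
    }
    l_new <- stats::uniroot(nd_median_gap, lower = m0$log_level - 3,
                            upper = m0$log_level + 3, tol = 1e-12)$root
    done <- abs(l_new - m0$log_level) < tol
    m0 <- gompertz_hazard(l_new, slope_fixed)
    if (done) break
  }
  if (!done) stop("rate-set calibration did not converge", call. = FALSE)
  inc <- calibrate_incidence(targets, m0, onset_age)
  rate_set(m0, mrr, inc, setting_label)
}

# Shipped defaults: the output of calibrate_rate_set() against the printed
# summary quantities of the two disease settings, frozen at full precision.
# high (type 2 diabetes like): risk 0.40019, median onset 60.75, median death
# of the non-diseased 74.00, onset age 30, MRR exp(2 - 0.02 a).
# low (lupus erythematosus like): risk 0.00196, median onset 32.55, median
# death of the non-diseased 70.53, onset age 18, MRR through (40, 3.79) and
# (80, 1.51).
.default_params <- list(
  high = list(
    m0 = c(log_level = -10.38322126726906, slope = 0.1),
    mrr = c(intercept = 2, decay = 0.02),
    incidence = c(onset_age = 30, log_level = -6.646115109689086,
                  slope = 0.037917071513996675),
    targets = c(lifetime_risk = 0.40019, median_onset = 60.75,
                median_death_nondiseased = 74.00)
  ),
  low = list(
    m0 = c(log_level = -9.721459244175831, slope = 0.1),
    mrr = c(intercept = 2.2526223873618374, decay = 0.023006409206687554),
    incidence = c(onset_age = 18, log_level = -8.681733614366243,
                  slope = -0.036720321566499757),
    targets = c(lifetime_risk = 0.00196, median_onset = 32.55,
                median_death_nondiseased = 70.53)
  )
)

#' Default rate sets for the high- and low-incidence settings
#'
#' Returns the shipped transition intensities for the two disease settings
#' studied by the package:
#'
#' * `"high"`: a common chronic disease (modelled on type 2 diabetes) with
#'   roughly 40% lifetime diagnosis risk, median onset 60.75 years, and true
#'   MRR \eqn{\exp(2 - 0.02a)} (3.32 / 2.23 / 1.49 at ages 40 / 60 / 80).
#' * `"low"`: a rare disease (modelled on lupus erythematosus) with roughly
#'   0.2% lifetime risk, median onset 32.55 years, and a log-linear true MRR
#'   through (40, 3.79) and (80, 1.51).
#'
#' The Gompertz and incidence parameters are the frozen output of
#' [calibrate_rate_set()] against those targets; pass `recalibrate = TRUE`
#' to re-run the calibration instead of using the stored values.
#'
#' @param setting `"high"` or `"low"`.
#' @param recalibrate Re-run the calibration instead of using the frozen
#'   parameters (slower; results agree to the calibration tolerance).
#' @return A [rate_set()].
#' @examples
#' mrr_value(default_rates("high")$mrr, c(40, 60, 80))
#' @export
default_rates <- function(setting = c("high", "low"), recalibrate = FALSE) {
  if (!is.character(setting) || length(setting) != 1L ||
      !setting %in% c("high", "low")) {
    stop('`setting` must be "high" or "low"', call. = FALSE)
  }
  p <- .default_params[[setting]]
  mrr <- loglinear_mrr(p$mrr[["intercept"]], p$mrr[["decay"]])
  if (recalibrate) {
    tg <- calibration_targets(p$targets[["lifetime_risk"]],
                              p$targets[["median_onset"]],
                              p$targets[["median_death_nondiseased"]])
    return(calibrate_rate_set(tg, mrr, p$incidence[["onset_age"]],
                              setting_label = setting))
  }
  rate_set(
    gompertz_hazard(p$m0[["log_level"]], p$m0[["slope"]]),
    mrr,
    incidence_curve(p$incidence[["onset_age"]], p$incidence[["log_level"]],
                    p$incidence[["slope"]]),
    setting_label = setting
  )
}

#' Read or write a rate set as a flat key-value config file
#'
#' Serialises a [rate_set()] to a YAML file with flat keys (`setting`,
#' `m0.log_level`, `m0.slope`, `mrr.intercept`, `mrr.decay`,
#' `incidence.onset_age`, `incidence.log_level`, `incidence.slope`) so users
#' can substitute their own transition-rate parametrisations. Values are
#' written at full double precision and round-trip exactly.
#'
#' @param rates A [rate_set()].
#' @param path File path.
#' @return `write_rates_config()` returns `path` invisibly;
#'   `read_rates_config()` returns a [rate_set()].
#' @export
write_rates_config <- function(rates, path) {
  stopifnot(inherits(rates, "rate_set"))
  num <- function(x) sprintf("%.17g", x) # full double precision, bit-exact
  x <- list(
    setting = rates$setting_label,
    m0.log_level = num(rates$m0$log_level),
    m0.slope = num(rates$m0$slope),
    mrr.intercept = num(rates$mrr$intercept),
    mrr.decay = num(rates$mrr$decay),
    incidence.onset_age = num(rates$incidence$onset_age),
    incidence.log_level = num(rates$incidence$log_level),
    incidence.slope = num(rates$incidence$slope)
  )
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_rates_config
#' @export
read_rates_config <- function(path) {
  x <- yaml::read_yaml(path)
  need <- c("setting", "m0.log_level", "m0.slope", "mrr.intercept",
            "mrr.decay", "incidence.onset_age", "incidence.log_level",
            "incidence.slope")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("rate config is missing keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  v <- function(k) as.numeric(x[[k]])
  rate_set(
    gompertz_hazard(v("m0.log_level"), v("m0.slope")),
    loglinear_mrr(v("mrr.intercept"), v("mrr.decay")),
    incidence_curve(v("incidence.onset_age"), v("incidence.log_level"),
                    v("incidence.slope")),
    setting_label = x$setting
  )
}
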