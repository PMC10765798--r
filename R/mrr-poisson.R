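#' Split life courses into person-time by state and one-year age band
#'
#' Converts life courses into the aggregated input of a Poisson person-time
#' rate regression: deaths and person-years at risk per disease group and
#' one-year age band inside the estimation window (default ages 40 to 80).
#' Classification follows the time split, not the status at death: an
#' individual diagnosed at 60 contributes non-diseased person-time before 60
#' and diseased person-time afterwards. Under the masked analysis
#' (`use_observed = TRUE`) the observed diagnosis age replaces the true one,
#' so undetected diagnoses contribute all their time -- and their death -- to
#' the non-diseased group. Deaths at or beyond the upper window edge are
#' censored at the edge and contribute no event.
#'
#' @param lives A tibble with `age_diagnosis`, `age_death` and, when
#'   `use_observed = TRUE`, `observed_diagnosis` (see [apply_micdad()]).
#' @param use_observed Use the survey-observed diagnosis age instead of the
#'   true one.
#' @param window Estimation window `c(lower, upper)` in years.
#' @param band_width Age band width in years; must divide the window.
#' @return A tibble with columns `group` (`"diseased"`/`"nondiseased"`),
#'   `band_start`, `events`, `person_years`, covering the full band grid for
#'   both groups (cells with no exposure have zero person-years and zero
#'   events).
#' @examples
#' lives <- tibble::tibble(age_diagnosis = 60, age_death = 70)
#' pt <- split_person_time(lives)
#' sum(pt$person_years[pt$group == "nondiseased"]) # 20 (ages 40-60)
#' sum(pt$person_years[pt$group == "diseased"])    # 10 (ages 60-70)
#' @export
split_person_time <- function(lives, use_observed = FALSE,
                              window = c(40, 80), band_width = 1) {
  if (!(is.numeric(window) && length(window) == 2L && window[1] < window[2])) {
    stop("`window` must be c(lower, upper) with lower < upper", call. = FALSE)
  }
  w0 <- window[1]
  w1 <- window[2]
  n_bands <- (w1 - w0) / band_width
  if (abs(n_bands - round(n_bands)) > 1e-9) {
    stop("`band_width` must divide the window", call. = FALSE)
  }
  n_bands <- as.integer(round(n_bands))
  stopifnot("age_death" %in% names(lives))
  eff <- if (use_observed) {
    if (!"observed_diagnosis" %in% names(lives)) {
      stop("`use_observed = TRUE` needs an `observed_diagnosis` column",
           call. = FALSE)
    }
    lives$observed_diagnosis
  } else {
    lives$age_diagnosis
  }
  eff[is.na(eff)] <- Inf
  death <- lives$age_death

  nd_hi <- pmin(eff, death, w1)            # nondiseased time is [w0, nd_hi)
  d_lo <- pmax(eff, w0)                    # diseased time is [d_lo, d_hi)
  d_hi <- pmin(death, w1)
  starts <- w0 + band_width * (seq_len(n_bands) - 1L)
  py_nd <- vapply(starts, function(b)
    sum(pmax(0, pmin(nd_hi, b + band_width) - b)), numeric(1))
  py_d <- vapply(starts, function(b)
    sum(pmax(0, pmin(d_hi, b + band_width) - pmax(d_lo, b))), numeric(1))

  in_win <- death >= w0 & death < w1
  band_idx <- floor((death[in_win] - w0) / band_width) + 1L
  died_diseased <- is.finite(eff[in_win])
  ev_d <- tabulate(band_idx[died_diseased], nbins = n_bands)
  ev_nd <- tabulate(band_idx[!died_diseased], nbins = n_bands)

  tibble::tibble(
    group = rep(c("nondiseased", "diseased"), each = n_bands),
    band_start = rep(starts, 2L),
    events = c(ev_nd, ev_d),
    person_years = c(py_nd, py_d)
  )
}

#' Fit a log-linear Poisson rate model to person-time cells
#'
#' Maximises the Poisson log-likelihood
#' \deqn{\sum_j d_j(\beta_0 + \beta_1 a_j + \log Y_j) -
#'   e^{\beta_0 + \beta_1 a_j} Y_j}
#' over the intercept and age slope, where \eqn{a_j} is the band midpoint,
#' \eqn{d_j} the deaths and \eqn{Y_j} the person-years of cell \eqn{j} --
#' i.e. a Poisson model with log link, age as the only covariate, and
#' log person-years as offset. Newton-Raphson from the intercept-only start
#' \eqn{\beta_0 = \log(\sum d / \sum Y)}, declared converged when the
#' parameter change drops below 1e-10. With a single informative band the
#' slope is fixed at zero and the rate is the closed-form
#' \eqn{\sum d / \sum Y}.
#'
#' @param cells Person-time cells for one group (see [split_person_time()]).
#' @param band_width Band width used to locate midpoints (default 1 year).
#' @return An object of class `poisson_rate_fit` with elements `coef`
#'   (`intercept`, `slope`), `vcov`, `converged`, `loglik`, `n_iter`,
#'   `nobs`, `events`. Supports [generics::tidy()] and [generics::glance()].
#' @export
fit_poisson_loglinear <- function(cells, band_width = 1) {
  stopifnot(all(c("band_start", "events", "person_years") %in% names(cells)))
  keep <- cells$person_years > 0
  d <- cells$events[keep]
  y <- cells$person_years[keep]
  a <- cells$band_start[keep] + band_width / 2
  if (any(cells$events[!keep] > 0)) {
    stop("events recorded in cells with zero person-years", call. = FALSE)
  }
  if (sum(d) == 0) {
    stop("no events: Poisson rate model cannot be fitted", call. = FALSE)
  }
  loglik_at <- function(b) sum(d * (b[1] + b[2] * a + log(y))) -
    sum(exp(b[1] + b[2] * a) * y)

  if (length(d) < 2L) {
    rate <- sum(d) / sum(y)
    b <- c(intercept = log(rate), slope = 0)
    vc <- matrix(c(1 / sum(d), NA, NA, NA), 2, 2,
                 dimnames = list(names(b), names(b)))
    return(structure(list(coef = b, vcov = vc, converged = TRUE,
                          loglik = loglik_at(b), n_iter = 0L,
                          nobs = length(d), events = sum(d)),
                     class = "poisson_rate_fit"))
  }

  b <- c(log(sum(d) / sum(y)), 0)
  converged <- FALSE
  info <- NULL
  iter <- 0L
  for (iter in 1:100) {
    mu <- exp(b[1] + b[2] * a) * y
    if (!all(is.finite(mu))) break
    score <- c(sum(d - mu), sum((d - mu) * a))
    info <- matrix(c(sum(mu), sum(mu * a), sum(mu * a), sum(mu * a^2)), 2, 2)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    # dampen wild early steps so the exponential never overflows
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    b <- b + step
    if (max(abs(step)) < 1e-10) {
      converged <- TRUE
      break
    }
  }
  names(b) <- c("intercept", "slope")
  vc <- if (!is.null(info)) {
    tryCatch(solve(info), error = function(e) matrix(NA_real_, 2, 2))
  } else matrix(NA_real_, 2, 2)
  dimnames(vc) <- list(names(b), names(b))
  structure(list(coef = b, vcov = vc, converged = converged,
                 loglik = loglik_at(b), n_iter = iter,
                 nobs = length(d), events = sum(d)),
            class = "poisson_rate_fit")
}

#' @export
print.poisson_rate_fit <- function(x, ...) {
  cat("<poisson_rate_fit> log rate =", format(x$coef[1]), "+",
      format(x$coef[2]), "* age\n")
  cat(" converged:", x$converged, " loglik:", format(x$loglik),
      " cells:", x$nobs, " events:", x$events, "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted Poisson rate model
#'
#' @param x A `poisson_rate_fit`.
#' @param ... Unused.
#' @return A tibble with one row per model term (`intercept`, `slope`) and
#'   columns `term`, `estimate`, `std.error`.
#' @export
tidy.poisson_rate_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coef),
                 estimate = unname(x$coef),
                 std.error = sqrt(diag(x$vcov)))
}

#' @rdname tidy.poisson_rate_fit
#' @return `glance()` returns a one-row tibble with `converged`, `loglik`,
#'   `n_iter`, `nobs`, `events`.
#' @export
glance.poisson_rate_fit <- function(x, ...) {
  tibble::tibble(converged = x$converged, loglik = x$loglik,
                 n_iter = x$n_iter, nobs = x$nobs, events = x$events)
}

#' Fitted mortality rate at given ages
#'
#' @param fit A `poisson_rate_fit`.
#' @param age Ages in years.
#' @return Per-year rates `exp(intercept + slope * age)`.
#' @export
rate_at <- function(fit, age) {
  stopifnot(inherits(fit, "poisson_rate_fit"))
  exp(fit$coef[[1]] + fit$coef[[2]] * age)
}

#' Mortality rate ratio curve from two fitted rate models
#'
#' Evaluates \eqn{\widehat{\mathrm{MRR}}(a) = \exp((\beta_{0,\mathrm{dis}} -
#' \beta_{0,\mathrm{non}}) + (\beta_{1,\mathrm{dis}} -
#' \beta_{1,\mathrm{non}})\,a)} at the requested ages, i.e. the ratio of
#' diseased to non-diseased fitted mortality rates.
#'
#' @param fit_diseased,fit_nondiseased Converged `poisson_rate_fit` objects.
#' @param ages Evaluation ages in years.
#' @return A tibble with columns `age`, `mrr` and `log_se` (delta-method
#'   standard error of the log ratio, from the two independent fits).
#' @export
mrr_curve <- function(fit_diseased, fit_nondiseased, ages = c(40, 60, 80)) {
  stopifnot(inherits(fit_diseased, "poisson_rate_fit"),
            inherits(fit_nondiseased, "poisson_rate_fit"))
  if (!fit_diseased$converged || !fit_nondiseased$converged) {
    stop("both Poisson fits must have converged", call. = FALSE)
  }
  db <- fit_diseased$coef - fit_nondiseased$coef
  var_log <- vapply(ages, function(a) {
    g <- c(1, a)
    as.numeric(g %*% fit_diseased$vcov %*% g + g %*% fit_nondiseased$vcov %*% g)
  }, numeric(1))
  tibble::tibble(age = ages,
                 mrr = exp(db[[1]] + db[[2]] * ages),
                 log_se = sqrt(var_log))
}

#' Estimate the age-dependent MRR from life courses in one call
#'
#' Convenience wrapper: splits person-time, fits the diseased and
#' non-diseased Poisson rate models separately, and evaluates the MRR curve.
#'
#' @inheritParams split_person_time
#' @param ages Evaluation ages.
#' @return The [mrr_curve()] tibble, with the two fits attached as
#'   attributes `fit_diseased` and `fit_nondiseased`.
#' @export
estimate_mrr <- function(lives, ages = c(40, 60, 80), use_observed = FALSE,
                         window = c(40, 80), band_width = 1) {
  cells <- split_person_time(lives, use_observed = use_observed,
                             window = window, band_width = band_width)
  fit_d <- fit_poisson_loglinear(cells[cells$group == "diseased", ],
                                 band_width = band_width)
  fit_n <- fit_poisson_loglinear(cells[cells$group == "nondiseased", ],
                                 band_width = band_width)
  out <- mrr_curve(fit_d, fit_n, ages)
  attr(out, "fit_diseased") <- fit_d
  attr(out, "fit_nondiseased") <- fit_n
  out
}
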