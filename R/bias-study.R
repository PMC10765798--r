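#' Configuration of the paired resampling bias study
#'
#' @param n_subpops Number of sub-populations to draw (default 200).
#' @param subpop_size Individuals per sub-population (default 5000).
#' @param eval_ages Ages at which the MRR is evaluated (default 40, 60, 80).
#' @param seed Integer seed for the sampling stream.
#' @param window Estimation window passed to [split_person_time()].
#' @return A `study_config` object.
#' @export
study_config <- function(n_subpops = 200L, subpop_size = 5000L,
                         eval_ages = c(40, 60, 80), seed = 1L,
                         window = c(40, 80)) {
  stopifnot(n_subpops >= 1, subpop_size >= 1,
            all(eval_ages >= window[1]), all(eval_ages <= window[2]))
  structure(list(n_subpops = as.integer(n_subpops),
                 subpop_size = as.integer(subpop_size),
                 eval_ages = eval_ages, seed = as.integer(seed),
                 window = window),
            class = "study_config")
}

#' Draw sub-populations from a simulated parent population
#'
#' Each draw is a simple random sample of `subpop_size` distinct individuals
#' taken without replacement from the parent population; the draws are
#' independent of one another, so different sub-populations may overlap.
#'
#' @param population Parent population tibble.
#' @param config A [study_config()].
#' @return A list of `n_subpops` integer row-index vectors.
#' @export
draw_subpopulations <- function(population, config) {
  stopifnot(inherits(config, "study_config"))
  n <- nrow(population)
  if (config$subpop_size > n) {
    stop("`subpop_size` exceeds the population size", call. = FALSE)
  }
  restore <- local_rng_seed(config$seed)
  on.exit(restore(), add = TRUE)
  lapply(seq_len(config$n_subpops),
         function(i) sample.int(n, config$subpop_size))
}

#' Run the paired with/without-MicDaD resampling study
#'
#' For every sub-population the MRR is estimated twice from the same
#' individuals: once from the true diagnosis ages and once after the
#' survey-based masking, giving a paired design. Sub-populations where any of
#' the four Poisson fits fails (for example no diseased deaths in a rare-
#' disease sample) are kept as rows with missing estimates and counted, not
#' dropped silently.
#'
#' @param population Parent population carrying `age_survey` and
#'   `observed_diagnosis` columns (see [assign_survey_ages()] and
#'   [apply_micdad()]).
#' @param config A [study_config()].
#' @return A tibble of class `micdad_study` with columns `subpop_id`, `age`,
#'   `mrr_without`, `mrr_with` and `diff = mrr_with - mrr_without`; the
#'   number of failed sub-population fits is attached as attribute
#'   `n_failed`.
#' @export
run_study <- function(population, config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  if (!all(c("age_survey", "observed_diagnosis") %in% names(population))) {
    stop("population must carry survey ages and observed diagnoses; ",
         "apply assign_survey_ages() and apply_micdad() first", call. = FALSE)
  }
  idx_sets <- draw_subpopulations(population, config)
  one <- function(k) {
    sub <- population[idx_sets[[k]], ]
    est <- function(use_observed) {
      tryCatch(
        estimate_mrr(sub, ages = config$eval_ages,
                     use_observed = use_observed, window = config$window)$mrr,
        error = function(e) rep(NA_real_, length(config$eval_ages)))
    }
    without <- est(FALSE)
    with_ <- est(TRUE)
    tibble::tibble(subpop_id = k, age = config$eval_ages,
                   mrr_without = without, mrr_with = with_,
                   diff = with_ - without)
  }
  out <- dplyr::bind_rows(lapply(seq_along(idx_sets), one))
  failed <- dplyr::filter(out, is.na(.data$diff))
  attr(out, "n_failed") <- length(unique(failed$subpop_id))
  class(out) <- c("micdad_study", class(out))
  out
}

#' Summarise the bias of MRR estimation under MicDaD
#'
#' Per evaluation age: medians and empirical 2.5% / 97.5% quantiles
#' (linear-interpolation, type-7 convention) of the MRR without masking, with
#' masking, and of their paired difference, together with counts of
#' sub-populations over- (`diff > 0`) and under-estimating (`diff < 0`) the
#' MRR, exact ties, and failed fits. The median difference is the bias
#' measure: negative values mean the MRR is underestimated in the presence of
#' misclassification.
#'
#' @param results A `micdad_study` tibble from [run_study()].
#' @return A tibble with one row per age.
#' @export
summarize_bias <- function(results) {
  stopifnot(all(c("age", "mrr_without", "mrr_with", "diff") %in%
                  names(results)))
  if (nrow(results) == 0L) stop("empty study results", call. = FALSE)
  q <- function(x, p) stats::quantile(x, p, na.rm = TRUE, names = FALSE,
                                      type = 7)
  dplyr::summarise(
    dplyr::group_by(results, .data$age),
    n_subpops = dplyr::n(),
    mrr_without_median = stats::median(.data$mrr_without, na.rm = TRUE),
    mrr_without_q025 = q(.data$mrr_without, 0.025),
    mrr_without_q975 = q(.data$mrr_without, 0.975),
    mrr_with_median = stats::median(.data$mrr_with, na.rm = TRUE),
    mrr_with_q025 = q(.data$mrr_with, 0.025),
    mrr_with_q975 = q(.data$mrr_with, 0.975),
    bias = stats::median(.data$diff, na.rm = TRUE),
    bias_q025 = q(.data$diff, 0.025),
    bias_q975 = q(.data$diff, 0.975),
    n_over = sum(.data$diff > 0, na.rm = TRUE),
    n_under = sum(.data$diff < 0, na.rm = TRUE),
    n_ties = sum(.data$diff == 0, na.rm = TRUE),
    n_failed = sum(is.na(.data$diff)),
    .groups = "drop"
  )
}

#' Gaussian kernel density of MRR estimates
#'
#' Thin wrapper around [stats::density()] with a Gaussian kernel and
#' Silverman's rule-of-thumb bandwidth, returning a tidy grid.
#'
#' @param values At least two finite values.
#' @param n Grid size.
#' @param ... Passed on to [stats::density()].
#' @return A tibble with columns `x` and `density`.
#' @export
mrr_density <- function(values, n = 512, ...) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) {
    stop("kernel density needs at least two finite values", call. = FALSE)
  }
  bw <- stats::bw.nrd0(values)
  # Silverman's rule degenerates to 0 for (near-)constant samples; floor it
  if (!is.finite(bw) || bw <= 0) bw <- 1e-3 * max(abs(values), 1)
  d <- stats::density(values, bw = bw, kernel = "gaussian", n = n, ...)
  tibble::tibble(x = d$x, density = d$y)
}
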