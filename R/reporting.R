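#' Format a bias summary in the style of the study tables
#'
#' One row per quantity (true MRR, MRR without MicDaD, MRR with MicDaD, bias,
#' and over/under-estimation counts), one column per evaluation age; medians
#' carry their 2.5%-97.5% quantile range in parentheses, all to 2 decimals.
#'
#' @param summary A tibble from [summarize_bias()].
#' @param true_mrr A [loglinear_mrr()] used to fill the true-MRR row.
#' @return A tibble of formatted character columns, one per age.
#' @export
render_tables <- function(summary, true_mrr) {
  stopifnot(inherits(true_mrr, "loglinear_mrr"))
  needed <- c("age", "mrr_without_median", "mrr_with_median", "bias")
  if (!all(needed %in% names(summary))) {
    stop("incomplete bias summary", call. = FALSE)
  }
  fmt <- function(m, lo, hi) sprintf("%.2f (%.2f-%.2f)", m, lo, hi)
  cols <- lapply(seq_len(nrow(summary)), function(i) {
    s <- summary[i, ]
    n_eval <- s$n_subpops - s$n_failed
    c(sprintf("%.2f", mrr_value(true_mrr, s$age)),
      fmt(s$mrr_without_median, s$mrr_without_q025, s$mrr_without_q975),
      fmt(s$mrr_with_median, s$mrr_with_q025, s$mrr_with_q975),
      fmt(s$bias, s$bias_q025, s$bias_q975),
      sprintf("%d (%.1f%%)", s$n_over, 100 * s$n_over / s$n_subpops),
      sprintf("%d (%.1f%%)", s$n_under, 100 * s$n_under / s$n_subpops))
  })
  out <- tibble::tibble(quantity = c(
    "True MRR (input for simulation)", "MRR without MicDaD",
    "MRR with MicDaD", "Bias", "MRR overestimated with MicDaD",
    "MRR underestimated with MicDaD"))
  for (i in seq_len(nrow(summary))) {
    out[[sprintf("%g years", summary$age[i])]] <- cols[[i]]
  }
  out
}

#' Plot the age-specific MRR of a rate set on a log scale
#'
#' @param rates A [rate_set()].
#' @param ages Age grid in years.
#' @return A ggplot object.
#' @export
plot_mrr_by_age <- function(rates, ages = seq(40, 80, by = 0.5)) {
  stopifnot(inherits(rates, "rate_set"))
  df <- tibble::tibble(age = ages, mrr = mrr_value(rates$mrr, ages))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$mrr)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Age (years)", y = "Mortality rate ratio (log scale)",
                  title = sprintf("Age-specific MRR (%s incidence setting)",
                                  rates$setting_label))
}

#' Density plot of MRR estimates with and without MicDaD
#'
#' Kernel density estimates of the sub-population MRR estimates at each
#' evaluation age, without masking (blue) and with masking (black), with the
#' individual estimates as rug marks and the true input MRR as a dashed line.
#'
#' @param object A `micdad_study` tibble from [run_study()].
#' @param true_mrr Optional [loglinear_mrr()] for the dashed reference line.
#' @param ... Unused.
#' @return A ggplot object, faceted by age.
#' @export
autoplot.micdad_study <- function(object, true_mrr = NULL, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object, "subpop_id", "age", "mrr_without", "mrr_with"),
    cols = c("mrr_without", "mrr_with"),
    names_to = "version", values_to = "mrr")
  long$version <- factor(long$version, c("mrr_without", "mrr_with"),
                         c("without MicDaD", "with MicDaD"))
  dens <- dplyr::reframe(
    dplyr::group_by(long, .data$age, .data$version),
    mrr_density(.data$mrr))
  p <- ggplot2::ggplot(dens,
                       ggplot2::aes(x = .data$x, y = .data$density,
                                    colour = .data$version)) +
    ggplot2::geom_line() +
    ggplot2::geom_rug(data = long,
                      ggplot2::aes(x = .data$mrr, y = NULL),
                      sides = "b", alpha = 0.3, length = ggplot2::unit(0.02, "npc")) +
    ggplot2::scale_colour_manual(values = c("without MicDaD" = "blue",
                                            "with MicDaD" = "black")) +
    ggplot2::facet_wrap(~.data$age, scales = "free",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Mortality rate ratio", y = "Kernel density",
                  colour = NULL)
  if (!is.null(true_mrr)) {
    ref <- tibble::tibble(age = unique(object$age))
    ref$mrr <- mrr_value(true_mrr, ref$age)
    p <- p + ggplot2::geom_vline(data = ref,
                                 ggplot2::aes(xintercept = .data$mrr),
                                 linetype = "dashed")
  }
  p
}

#' Run the full MicDaD simulation pipeline end to end
#'
#' Executes simulate, survey/mask, sub-sample, estimate and summarise for one
#' disease setting and writes all artifacts to `out_dir`: the Lexis-format
#' population CSV, the surveyed-population CSV, the per-sub-population study
#' CSV, the bias-summary CSV, a formatted table, the two figures (age-specific
#' MRR on a log scale; MRR densities with rug marks), and a YAML run manifest
#' from which the run can be reproduced exactly. A single top-level seed is
#' expanded into independent named sub-streams for the simulation, survey and
#' sampling stages. Numeric CSV values are rounded to 10 significant digits
#' so outputs are byte-stable across platforms.
#'
#' @param setting `"high"` or `"low"`.
#' @param out_dir Output directory (created if needed).
#' @param seed Top-level integer seed.
#' @param n_individuals,n_subpops,subpop_size Study sizes.
#' @param rates Optional [rate_set()] overriding the setting default.
#' @param config_file Optional rate-set YAML (see [read_rates_config()])
#'   overriding both.
#' @param write_figures Write the PDF figures (default `TRUE`).
#' @return The run manifest, invisibly, as a named list.
#' @export
run_pipeline <- function(setting = c("high", "low"), out_dir, seed = 1L,
                         n_individuals = 100000L, n_subpops = 200L,
                         subpop_size = 5000L, rates = NULL,
                         config_file = NULL, write_figures = TRUE) {
  if (!is.null(config_file)) {
    rates <- read_rates_config(config_file)
    setting <- rates$setting_label
  } else {
    setting <- match.arg(setting)
    if (is.null(rates)) rates <- default_rates(setting)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  pop <- simulate_population(rates, n = n_individuals,
                             seed = derive_seed(seed, "simulation"))
  pop <- assign_survey_ages(pop, seed = derive_seed(seed, "survey"))
  pop <- apply_micdad(pop)
  cfg <- study_config(n_subpops = n_subpops, subpop_size = subpop_size,
                      seed = derive_seed(seed, "sampling"))
  study <- run_study(pop, cfg)
  summary <- summarize_bias(study)

  round10 <- function(df) dplyr::mutate(df, dplyr::across(
    dplyr::where(is.double), ~ signif(.x, 10)))
  paths <- list(
    lexis = file.path(out_dir, "population_lexis.csv"),
    surveyed = file.path(out_dir, "population_surveyed.csv"),
    study = file.path(out_dir, "study_subpopulations.csv"),
    summary = file.path(out_dir, "bias_summary.csv"),
    table = file.path(out_dir, "bias_table.csv"),
    manifest = file.path(out_dir, "manifest.yaml")
  )
  readr::write_csv(round10(as_lexis(pop)), paths$lexis)
  readr::write_csv(round10(pop), paths$surveyed)
  readr::write_csv(round10(tibble::as_tibble(study)), paths$study)
  readr::write_csv(round10(summary), paths$summary)
  readr::write_csv(render_tables(summary, rates$mrr), paths$table)
  if (write_figures) {
    paths$fig_mrr <- file.path(out_dir, "mrr_by_age.pdf")
    paths$fig_density <- file.path(out_dir, "mrr_density.pdf")
    ggplot2::ggsave(paths$fig_mrr, plot_mrr_by_age(rates),
                    width = 6, height = 4)
    ggplot2::ggsave(paths$fig_density,
                    autoplot.micdad_study(study, true_mrr = rates$mrr),
                    width = 9, height = 4)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("micdad")),
    setting = setting,
    seed = as.integer(seed),
    seeds = list(simulation = derive_seed(seed, "simulation"),
                 survey = derive_seed(seed, "survey"),
                 sampling = derive_seed(seed, "sampling")),
    n_individuals = as.integer(n_individuals),
    n_subpops = as.integer(n_subpops),
    subpop_size = as.integer(subpop_size),
    rates = list(setting = rates$setting_label,
                 m0.log_level = rates$m0$log_level,
                 m0.slope = rates$m0$slope,
                 mrr.intercept = rates$mrr$intercept,
                 mrr.decay = rates$mrr$decay,
                 incidence.onset_age = rates$incidence$onset_age,
                 incidence.log_level = rates$incidence$log_level,
                 incidence.slope = rates$incidence$slope),
    outputs = lapply(paths, normalizePath, mustWork = FALSE)
  )
  yaml::write_yaml(manifest, paths$manifest, precision = 17)
  invisible(manifest)
}
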