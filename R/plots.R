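#' Forest plot of risk-score correlations and associations
#'
#' Draws the 5 x 3 grid of estimates with their confidence intervals,
#' correlations and per-adjusted-SD associations side by side.
#'
#' @param object A `prs_analysis` from [run_prs_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot prs_analysis
#' @export
autoplot.prs_analysis <- function(object, ...) {
  tab <- dplyr::bind_rows(
    dplyr::mutate(object$correlations, kind = "correlation"),
    dplyr::mutate(object$associations, kind = "association (per adjusted SD)")
  )
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$estimate, y = .data$outcome,
                                    colour = .data$predictor)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::facet_wrap(~kind, scales = "free_x") +
    ggplot2::labs(x = "estimate (95% CI)", y = NULL, colour = "PRS endpoint") +
    ggplot2::theme_minimal()
}

#' Summary plot of a SNP association screen
#'
#' Shows, per mammogram risk score, the distribution of per-SNP
#' -log10 p-values with the nominal threshold and the expected chance
#' count annotated.
#'
#' @param object A `snp_screen` from [run_snp_screen()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot snp_screen
#' @export
autoplot.snp_screen <- function(object, ...) {
  tab <- dplyr::mutate(object$per_snp, neglog_p = -log10(.data$p.value))
  thr <- -log10(object$alpha)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$outcome, y = .data$neglog_p)) +
    ggplot2::geom_jitter(width = 0.2, height = 0, alpha = 0.5,
                         ggplot2::aes(colour = .data$direction_consistent)) +
    ggplot2::geom_hline(yintercept = thr, linetype = 2) +
    ggplot2::labs(x = NULL, y = expression(-log[10](p)),
                  colour = "direction-consistent") +
    ggplot2::theme_minimal()
}

#' Attenuation plot for mutually adjusted associations
#'
#' @param object A `mutual_adjustment` tibble from
#'   [run_mutual_adjustment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mutual_adjustment
#' @export
autoplot.mutual_adjustment <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$estimate, y = .data$adjusted_for,
                               colour = .data$predictor)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::facet_wrap(~outcome) +
    ggplot2::labs(x = "adjusted association (per adjusted SD)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Distributions of the raw density measures
#'
#' Histograms of the five density measures on their raw scale, faceted by
#' measure — a quick check that simulated (or imported) data have the
#' right magnitudes and skew.
#'
#' @param data Cohort tibble with the density columns.
#' @return A ggplot object.
#' @export
plot_density_measures <- function(data) {
  if (!all(c("cumulus_percent", "cumulus_white") %in% names(data))) {
    data <- derive_measures(data)
  }
  long <- tidyr::pivot_longer(
    data,
    dplyr::all_of(c("cumulus", "cumulus_percent", "altocumulus",
                    "cirrocumulus", "cumulus_white")),
    names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::facet_wrap(~measure, scales = "free") +
    ggplot2::labs(x = NULL, y = "women") +
    ggplot2::theme_minimal()
}
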