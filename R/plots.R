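#' Fold-change overview of differential features
#'
#' Horizontal bar chart of log2 fold changes for the selected features,
#' colored by enrichment direction — the standard overview of which
#' species (or reactions) go up or down in disease.
#'
#' @param results a differential-result tibble
#'   (from [differential_abundance()] or [select_significant_msps()]),
#'   optionally with a `disease` column for faceting.
#' @return a ggplot object.
#' @export
plot_fold_change <- function(results) {
  p <- ggplot2::ggplot(results,
                       ggplot2::aes(x = .data$fold_change,
                                    y = stats::reorder(.data$feature_id,
                                                       .data$fold_change),
                                    fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c("disease-enriched" = "#c0392b",
                                          "control-enriched" = "#2980b9")) +
    ggplot2::labs(x = "log2 fold change (case vs control)", y = NULL,
                  fill = NULL) +
    ggplot2::theme_minimal()
  if ("disease" %in% names(results))
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$disease))
  p
}

#' Group-average exchange flux comparison
#'
#' Paired bars of mean exchange flux per metabolite for disease-enriched vs
#' control-enriched models (negative = consumed, positive = secreted).
#'
#' @param avg output of [group_average_flux()] (columns `metabolite_id`,
#'   `group`, `mean_flux`).
#' @param metabolites optional metabolite ids to restrict to (e.g. the
#'   short-chain fatty acids).
#' @return a ggplot object.
#' @export
plot_group_flux <- function(avg, metabolites = NULL) {
  if (!is.null(metabolites))
    avg <- dplyr::filter(avg, .data$metabolite_id %in% metabolites)
  ggplot2::ggplot(avg, ggplot2::aes(x = .data$metabolite_id,
                                    y = .data$mean_flux,
                                    fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "mean exchange flux (mmol/gDW/h)",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Reaction abundance split by BMI stratum
#'
#' Boxplots of per-sample reaction abundance for obese (BMI above the cut)
#' vs non-obese samples, one panel per reaction.
#'
#' @param ra reaction-abundance table (tibble with `sample_id`).
#' @param meta metadata with `sample_id` and `bmi`.
#' @param reactions reaction ids to show.
#' @param bmi_cut BMI boundary (default 30).
#' @return a ggplot object.
#' @export
plot_bmi_split <- function(ra, meta, reactions, bmi_cut = 30) {
  long <- ra |>
    dplyr::select(dplyr::all_of(c("sample_id", intersect(reactions, names(ra))))) |>
    tidyr::pivot_longer(-"sample_id", names_to = "reaction_id",
                        values_to = "abundance") |>
    dplyr::inner_join(meta[, c("sample_id", "bmi")], by = "sample_id") |>
    dplyr::mutate(stratum = ifelse(.data$bmi > bmi_cut,
                                   paste0("BMI > ", bmi_cut),
                                   paste0("BMI ≤ ", bmi_cut)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stratum, y = .data$abundance,
                                     fill = .data$stratum)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$reaction_id), scales = "free_y") +
    ggplot2::scale_fill_manual(values = stats::setNames(
      c("#e75480", "#5dade2"),
      c(paste0("BMI > ", bmi_cut), paste0("BMI ≤ ", bmi_cut)))) +
    ggplot2::labs(x = NULL, y = "reaction abundance", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fba_result <- function(object, n = 20, ...) {
  fluxes <- tidy(object)
  fluxes <- dplyr::slice_max(fluxes, abs(.data$flux), n = n)
  ggplot2::ggplot(fluxes, ggplot2::aes(x = .data$flux,
                                       y = stats::reorder(.data$reaction_id,
                                                          .data$flux))) +
    ggplot2::geom_col(fill = "#34495e") +
    ggplot2::labs(x = "flux (mmol/gDW/h)", y = NULL,
                  title = paste("FBA solution:", object$model_id)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
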