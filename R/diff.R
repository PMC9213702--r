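#' Two-tailed Wilcoxon rank-sum p-value
#'
#' The workhorse test for case/control comparison of abundances. Uses exact
#' enumeration when the pooled sample size is at most 20 and there are no
#' ties, and otherwise the normal approximation with tie and continuity
#' correction. A pooled sample with zero spread (every value identical)
#' carries no evidence and returns p = 1.
#'
#' @param x,y numeric vectors for the two groups (each nonempty).
#' @return the two-sided p-value.
#' @export
wilcoxon_two_sided <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L)
    stop("both groups must be nonempty")
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) return(1)
  exact <- (length(pooled) <= 20L) && !anyDuplicated(pooled)
  p <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE)$p.value)
  if (is.na(p)) 1 else min(p, 1)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted values on the same order; monotone in the sorted order,
#'   never below the raw value, capped at 1.
#' @export
benjamini_hochberg <- function(p) {
  p <- as.numeric(p)
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Enrichment direction from group means
#'
#' A feature is called disease-enriched when its mean abundance in cases
#' strictly exceeds the mean in controls; exact ties fall to
#' control-enriched (and are worth flagging upstream).
#'
#' @param mean_case,mean_control numeric vectors of group means.
#' @return character vector, `"disease-enriched"` or `"control-enriched"`.
#' @export
enrichment_direction <- function(mean_case, mean_control) {
  ifelse(mean_case > mean_control, "disease-enriched", "control-enriched")
}

#' Differential abundance of features between cases and controls
#'
#' Per-feature two-tailed Wilcoxon rank-sum with Benjamini-Hochberg FDR,
#' group medians and means, a log2 fold change with a pseudo-count of half
#' the smallest nonzero value in the table, and the enrichment direction by
#' mean comparison. This one engine serves both species (MSP) level and
#' reaction level analysis.
#'
#' @param tbl a samples-by-features table: a tibble whose first column is
#'   `sample_id`, or a numeric matrix with sample rownames.
#' @param meta a tibble with columns `sample_id` and `group`
#'   (`"case"` / `"control"`).
#' @return a tibble with one row per feature: `feature_id`, `p_value`,
#'   `fdr`, `median_case`, `median_control`, `mean_case`, `mean_control`,
#'   `fold_change`, `direction`.
#' @export
differential_abundance <- function(tbl, meta) {
  m <- if (is.matrix(tbl)) tbl else table_to_matrix(tbl)
  stopifnot(all(c("sample_id", "group") %in% names(meta)))
  meta <- meta[meta$sample_id %in% rownames(m), ]
  case_ids <- meta$sample_id[meta$group == "case"]
  ctrl_ids <- meta$sample_id[meta$group == "control"]
  if (length(case_ids) < 2L || length(ctrl_ids) < 2L)
    stop("need at least 2 case and 2 control samples")
  mc <- m[case_ids, , drop = FALSE]
  mh <- m[ctrl_ids, , drop = FALSE]
  p <- vapply(seq_len(ncol(m)),
              function(j) wilcoxon_two_sided(mc[, j], mh[, j]), 0)
  nonzero <- m[m > 0]
  eps <- if (length(nonzero)) min(nonzero) / 2 else 1e-9
  mean_case <- colMeans(mc)
  mean_control <- colMeans(mh)
  tibble::tibble(
    feature_id = colnames(m),
    p_value = p,
    fdr = benjamini_hochberg(p),
    median_case = apply(mc, 2, stats::median),
    median_control = apply(mh, 2, stats::median),
    mean_case = unname(mean_case),
    mean_control = unname(mean_control),
    fold_change = log2((mean_case + eps) / (mean_control + eps)),
    direction = enrichment_direction(mean_case, mean_control))
}

#' Two-step selection of significant MSPs
#'
#' Applies the species-selection rule: (1) FDR below the threshold, and
#' (2) distinctly different medians between patients and controls — one
#' group's median exactly 0 while the other's is strictly positive. The
#' zero-median requirement targets species that are effectively absent from
#' one group.
#'
#' @param tbl samples-by-MSP abundance table (tibble with `sample_id`
#'   column, or matrix).
#' @param meta sample metadata with `sample_id` and `group`.
#' @param fdr_threshold significance threshold on the BH-adjusted p
#'   (default 0.01).
#' @return the differential-abundance tibble restricted to selected MSPs.
#' @export
select_significant_msps <- function(tbl, meta, fdr_threshold = 0.01) {
  res <- differential_abundance(tbl, meta)
  dplyr::filter(res,
                .data$fdr < fdr_threshold,
                xor(.data$median_case == 0, .data$median_control == 0),
                pmax(.data$median_case, .data$median_control) > 0)
}

#' Aggregate an abundance table to phylum level
#'
#' @param tbl samples-by-MSP table (tibble with `sample_id` column, or
#'   matrix).
#' @param taxonomy either a named character vector (feature id -> phylum),
#'   a tibble with columns `feature_id`, `phylum`, or a list of `gem`s
#'   whose taxonomy supplies the phylum. Unlabelled features fall into
#'   `"unclassified"`.
#' @return a tibble `sample_id` + one column per phylum, each the sum of
#'   member MSP abundances.
#' @export
aggregate_by_phylum <- function(tbl, taxonomy) {
  m <- if (is.matrix(tbl)) tbl else table_to_matrix(tbl)
  phy <- phylum_lookup(taxonomy)
  lab <- unname(phy[colnames(m)])
  lab[is.na(lab)] <- "unclassified"
  agg <- t(rowsum(t(m), group = lab))
  matrix_to_table(agg[, sort(colnames(agg)), drop = FALSE])
}

phylum_lookup <- function(taxonomy) {
  if (is.list(taxonomy) && all(vapply(taxonomy, inherits, TRUE, "gem"))) {
    stats::setNames(vapply(taxonomy, function(g) g$taxonomy[["phylum"]], ""),
                    vapply(taxonomy, `[[`, "", "id"))
  } else if (is.data.frame(taxonomy)) {
    stats::setNames(taxonomy$phylum, taxonomy$feature_id)
  } else {
    taxonomy
  }
}

#' Union of per-disease feature selections
#'
#' Pools the features selected in each disease and removes duplicates,
#' yielding the unique significant set across disorders.
#'
#' @param per_disease a list (possibly named by disease) of character
#'   vectors of feature ids.
#' @return sorted character vector of the union.
#' @export
unique_union <- function(per_disease) {
  stopifnot(length(per_disease) >= 1L)
  sort(unique(unlist(per_disease, use.names = FALSE)))
}
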