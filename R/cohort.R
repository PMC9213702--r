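#' Cohort design tables of the metabolic-disease metagenome studies
#'
#' The package ships the study-design tables of the six public case/control
#' metagenome cohorts (type 2 diabetes, obesity and atherosclerotic
#' cardiovascular disease): a per-cohort overview with sample counts and
#' accessions, and per-disease subject metadata. They serve as reference
#' inputs for cohort arithmetic; the underlying sequence data themselves
#' are external.
#'
#' @return a tibble (`cohort_overview()`: one row per cohort;
#'   `cohort_metadata()`: one row per disease and group).
#' @export
cohort_overview <- function() {
  read_tsv_quiet(system.file("extdata", "cohort_overview.tsv",
                             package = "gutflux", mustWork = TRUE))
}

#' @rdname cohort_overview
#' @export
cohort_metadata <- function() {
  read_tsv_quiet(system.file("extdata", "cohort_metadata.tsv",
                             package = "gutflux", mustWork = TRUE))
}

#' Sum the cohort tables into study-level counts
#'
#' Computes the totals the study design implies: overall subjects (sum of
#' the per-disease case and control totals) and per-disease case counts
#' summed over cohorts. The per-cohort and per-disease tables disagree on
#' the T2D case count (71 + 93 from the cohort overview vs 271 in the
#' subject metadata); both numbers are reported and no reconciliation is
#' attempted.
#'
#' @return a named list of counts: `total_subjects`, `obesity_cases`,
#'   `acvd_cases`, `t2d_cases_by_cohort`, `t2d_cases_by_disease`.
#' @export
cohort_counts <- function() {
  ov <- cohort_overview()
  md <- cohort_metadata()
  case_by_disease <- function(d) sum(ov$n_case[ov$disease == d])
  list(
    total_subjects = sum(md$total),
    obesity_cases = case_by_disease("obesity"),
    acvd_cases = case_by_disease("ACVD"),
    t2d_cases_by_cohort = case_by_disease("T2D"),
    t2d_cases_by_disease = sum(md$total[md$disease == "T2D" & md$group == "case"]))
}
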