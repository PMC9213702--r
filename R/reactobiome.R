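#' Per-sample reaction abundance (the "reactobiome")
#'
#' Personalizes metabolic capacity to each sample: the abundance of a
#' reaction in a sample is the summed relative abundance of all species
#' whose models carry that reaction — the matrix product of the
#' samples-by-species abundance table with the binary species-by-reaction
#' presence matrix. Presence is binary: per-model reaction copy number does
#' not enter.
#'
#' @param presence binary species x reaction matrix from
#'   [reaction_presence()].
#' @param abundance samples-by-species table (tibble with `sample_id`
#'   column, or matrix). Species in the abundance table without a model
#'   simply contribute nothing; species in `presence` missing from the
#'   abundance table trigger a warning and are dropped.
#' @return a tibble `sample_id` + one nonnegative column per reaction.
#' @export
compute_reaction_abundance <- function(presence, abundance) {
  a <- if (is.matrix(abundance)) abundance else table_to_matrix(abundance)
  missing <- setdiff(rownames(presence), colnames(a))
  if (length(missing))
    warning("species with models but no abundance: ",
            paste(missing, collapse = ", "), call. = FALSE)
  common <- intersect(rownames(presence), colnames(a))
  if (length(common) == 0L)
    stop("no overlap between modelled species and abundance table")
  ra <- a[, common, drop = FALSE] %*% presence[common, , drop = FALSE]
  matrix_to_table(ra)
}

#' Differential reaction abundance between cases and controls
#'
#' Runs the shared Wilcoxon + Benjamini-Hochberg engine
#' ([differential_abundance()]) over a reaction-abundance table.
#'
#' @param ra reaction-abundance table from [compute_reaction_abundance()].
#' @param meta sample metadata with `sample_id` and `group`.
#' @return a differential-result tibble (one row per reaction; the
#'   `feature_id` column holds reaction ids).
#' @export
differential_reactions <- function(ra, meta) {
  differential_abundance(ra, meta)
}

#' Reactions significant in every disease
#'
#' @param per_disease named list (one element per disease) of
#'   differential-result tibbles from [differential_reactions()].
#' @param fdr_threshold per-disease significance threshold (default 0.01).
#' @return character vector of reaction ids with `fdr < fdr_threshold` in
#'   all diseases.
#' @export
intersect_significant <- function(per_disease, fdr_threshold = 0.01) {
  stopifnot(length(per_disease) >= 2L)
  sets <- lapply(per_disease, function(res)
    res$feature_id[res$fdr < fdr_threshold])
  sort(Reduce(intersect, sets))
}

#' Reactions enriched in disease consistently across diseases
#'
#' @param per_disease named list of differential-result tibbles.
#' @param reactions candidate reaction ids (typically the output of
#'   [intersect_significant()]).
#' @return the subset of `reactions` whose direction is
#'   `"disease-enriched"` in every disease.
#' @export
consistent_direction <- function(per_disease, reactions) {
  keep <- vapply(reactions, function(r) {
    all(vapply(per_disease, function(res) {
      i <- match(r, res$feature_id)
      !is.na(i) && res$direction[i] == "disease-enriched"
    }, TRUE))
  }, TRUE)
  sort(reactions[keep])
}

#' Build a reaction -> KEGG-ortholog map from model annotations
#'
#' @param gems list of `gem`s; KO annotations are unioned across models for
#'   each reaction id.
#' @return a tibble `reaction_id`, `ko` (list-column of KO ids, possibly
#'   empty).
#' @export
ko_map <- function(gems) {
  gems <- as_gem_list(gems)
  entries <- purrr::map_dfr(gems, function(g)
    tibble::tibble(reaction_id = names(g$reactions),
                   ko = lapply(g$reactions, `[[`, "ko")))
  entries |>
    tidyr::unnest_longer("ko", keep_empty = TRUE) |>
    dplyr::distinct() |>
    dplyr::group_by(.data$reaction_id) |>
    dplyr::summarise(ko = list(sort(unique(stats::na.omit(.data$ko)))),
                     .groups = "drop")
}

#' Map a reaction set to KEGG orthologs
#'
#' @param reactions character vector of reaction ids.
#' @param komap a tibble `reaction_id` / `ko` (list-column) as produced by
#'   [ko_map()].
#' @return a list with `kos` (deduplicated union of KO ids) and `unmapped`
#'   (reactions without any KO annotation).
#' @export
map_to_kos <- function(reactions, komap) {
  idx <- match(reactions, komap$reaction_id)
  ann <- komap$ko[idx]
  ann[is.na(idx)] <- list(character())
  n_ko <- vapply(ann, length, 0L)
  list(kos = sort(unique(unlist(ann))),
       unmapped = sort(reactions[n_ko == 0L]))
}

#' Filter reactions by model-presence gap between enrichment groups
#'
#' Keeps reactions whose presence fraction differs by more than `min_gap`
#' between disease-enriched and control-enriched models — reactions that
#' preferentially live in one side of the dysbiosis.
#'
#' @param presence binary species x reaction matrix.
#' @param model_groups tibble with `model_id` and `group`
#'   (`"disease-enriched"` / `"control-enriched"`).
#' @param min_gap minimal absolute difference in presence fractions
#'   (default 0.2, i.e. over 20%).
#' @return character vector of retained reaction ids.
#' @export
presence_gap_filter <- function(presence, model_groups, min_gap = 0.2) {
  stopifnot(all(c("model_id", "group") %in% names(model_groups)))
  enr <- model_groups$model_id[model_groups$group == "disease-enriched"]
  dep <- model_groups$model_id[model_groups$group == "control-enriched"]
  enr <- intersect(enr, rownames(presence))
  dep <- intersect(dep, rownames(presence))
  if (length(enr) == 0L || length(dep) == 0L)
    stop("both enrichment groups must contain at least one model")
  gap <- abs(colMeans(presence[enr, , drop = FALSE]) -
               colMeans(presence[dep, , drop = FALSE]))
  sort(colnames(presence)[gap > min_gap])
}

#' Differential KO abundance (optional KO-level re-test)
#'
#' Collapses reaction abundance to KO level (KO abundance = sum of member
#' reaction abundances) and re-runs the Wilcoxon + BH engine. This is the
#' alternative reading of "significant KOs" to the plain annotation union
#' of [map_to_kos()].
#'
#' @param ra reaction-abundance table.
#' @param komap tibble `reaction_id` / `ko` from [ko_map()].
#' @param meta sample metadata with `sample_id` and `group`.
#' @return differential-result tibble with KO ids in `feature_id`.
#' @export
differential_kos <- function(ra, komap, meta) {
  m <- table_to_matrix(ra)
  long <- komap |>
    tidyr::unnest_longer("ko") |>
    dplyr::filter(!is.na(.data$ko), .data$reaction_id %in% colnames(m))
  if (nrow(long) == 0L) stop("no annotated reactions in the table")
  ko_ids <- sort(unique(long$ko))
  koM <- vapply(ko_ids, function(k) {
    rs <- long$reaction_id[long$ko == k]
    rowSums(m[, rs, drop = FALSE])
  }, numeric(nrow(m)))
  rownames(koM) <- rownames(m)
  differential_abundance(koM, meta)
}
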