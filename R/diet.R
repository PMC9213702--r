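#' Define a diet (medium) for constraint-based simulation
#'
#' A diet is the nutritional boundary condition of a simulation: for each
#' external metabolite, the maximal rate at which a model may take it up
#' (mmol/gDW/h). Metabolites absent from the diet cannot be taken up at all;
#' secretion is never limited by the diet. The `anaerobic` flag closes
#' oxygen uptake regardless of any oxygen entry in the table, matching gut
#' conditions.
#'
#' @param uptake_limits named numeric vector: external metabolite id ->
#'   maximal uptake rate (nonnegative).
#' @param anaerobic logical; close oxygen uptake (default `TRUE`, the gut is
#'   anaerobic).
#' @return an object of class `diet`.
#' @export
diet <- function(uptake_limits, anaerobic = TRUE) {
  uptake_limits <- unlist(uptake_limits)
  if (is.null(names(uptake_limits)) || any(!nzchar(names(uptake_limits))))
    stop("uptake_limits must be a named vector of metabolite ids")
  if (any(uptake_limits < 0)) stop("diet uptake rates must be nonnegative")
  structure(list(uptake_limits = uptake_limits,
                 anaerobic = isTRUE(anaerobic)),
            class = "diet")
}

#' @export
print.diet <- function(x, ...) {
  cat("<diet> ", length(x$uptake_limits), " metabolites, ",
      if (x$anaerobic) "anaerobic" else "aerobic", "\n", sep = "")
  invisible(x)
}

#' Read / write a diet TSV
#'
#' The format has columns `metabolite_id` and `max_uptake_mmol_gDW_h`, a
#' header row, and optional `#` comment lines.
#'
#' @param path file path.
#' @param anaerobic logical, stored on the returned object (the flag is a
#'   run-time switch, not part of the file).
#' @return a `diet` (for `read_diet`); `path` invisibly (for `write_diet`).
#' @export
read_diet <- function(path, anaerobic = TRUE) {
  if (!file.exists(path)) stop("no such diet file: ", path)
  tbl <- read_tsv_quiet(path)
  need <- c("metabolite_id", "max_uptake_mmol_gDW_h")
  if (!all(need %in% names(tbl)))
    stop("diet file must have columns ", paste(need, collapse = ", "))
  diet(stats::setNames(tbl$max_uptake_mmol_gDW_h, tbl$metabolite_id),
       anaerobic = anaerobic)
}

#' @rdname read_diet
#' @param x a `diet`.
#' @export
write_diet <- function(x, path) {
  stopifnot(inherits(x, "diet"))
  write_tsv_quiet(tibble::tibble(metabolite_id = names(x$uptake_limits),
                                 max_uptake_mmol_gDW_h = unname(x$uptake_limits)),
                  path)
}

#' A synthetic high-fibre omnivore diet
#'
#' A documented stand-in medium in the spirit of a high-fibre omnivore diet:
#' fermentable sugars (glucose, fructose, sucrose, starch), amino acids
#' (glutamate, glycine, alanine, serine and others), tartrate, ammonia and
#' minerals, with anaerobic conditions. Rates are mmol/gDW/h. The exact
#' composition used with real gut models is a user input; this one is
#' matched to the metabolite namespace of the synthetic toy models shipped
#' with the package.
#'
#' @param anaerobic logical, default `TRUE`.
#' @return a `diet`.
#' @export
high_fibre_diet <- function(anaerobic = TRUE) {
  diet(c(
    glc_e = 10, fru_e = 5, sucr_e = 5, starch_e = 5,
    glu_e = 5, gly_e = 2, ala_e = 2, ser_e = 2,
    tar_e = 2, nh3_e = 5,
    pi_e = 10, k_e = 10, mg_e = 10, h2o_e = 100
  ), anaerobic = anaerobic)
}
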