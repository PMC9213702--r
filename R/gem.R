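#' Construct a genome-scale metabolic model (GEM)
#'
#' A `gem` is the unit of metabolic modelling here: the stoichiometric
#' reconstruction of one metagenomic species pan-genome (MSP), with reaction
#' bounds, a biomass objective and exchange reactions through which the
#' species takes up and secretes metabolites. Metabolite identity is by
#' string id in a namespace shared across models, which is what makes
#' cross-model comparison and community merging possible.
#'
#' @param id model identifier (conventionally the MSP id).
#' @param taxonomy named character vector of rank = name; must include
#'   `phylum`.
#' @param metabolites a data frame with columns `id`, `name`, `compartment`
#'   and optionally `formula`, `kegg`.
#' @param reactions a list of reactions, each a list with elements `id`,
#'   `stoich` (named numeric, negative = consumed), `lb`, `ub`, and
#'   optionally `ko` (character vector of KEGG orthologs) and `subsystem`.
#' @param biomass_reaction id of the biomass reaction (the growth objective).
#' @param exchanges character vector of exchange reaction ids; each exchange
#'   must involve exactly one metabolite, with coefficient -1 on the
#'   external species so that negative flux is uptake and positive flux is
#'   secretion.
#'
#' @return An object of class `gem`.
#' @export
gem <- function(id, taxonomy, metabolites, reactions, biomass_reaction,
                exchanges) {
  metabolites <- tibble::as_tibble(metabolites)
  for (col in c("formula", "kegg")) {
    if (!col %in% names(metabolites)) metabolites[[col]] <- NA_character_
  }
  reactions <- lapply(reactions, function(r) {
    list(id = r$id,
         stoich = unlist(r$stoich),
         lb = as.numeric(r$lb),
         ub = as.numeric(r$ub),
         ko = as.character(r$ko %||% character()),
         subsystem = r$subsystem %||% NA_character_)
  })
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  x <- structure(
    list(id = id,
         taxonomy = taxonomy,
         metabolites = metabolites,
         reactions = reactions,
         biomass_reaction = biomass_reaction,
         exchanges = sort(unique(as.character(exchanges)))),
    class = "gem")
  validate_gem(x)
  x
}

#' Validate a GEM against its structural invariants
#'
#' Checks id uniqueness, that every stoichiometry entry resolves to a
#' declared metabolite, finite nonzero coefficients, ordered bounds, the
#' existence of the biomass reaction, and the single-metabolite exchange
#' convention.
#'
#' @param x a `gem`.
#' @return `x`, invisibly; errors describe every violation found.
#' @export
validate_gem <- function(x) {
  stopifnot(inherits(x, "gem"))
  problems <- character()
  met_ids <- x$metabolites$id
  if (any(!nzchar(met_ids))) problems <- c(problems, "empty metabolite id")
  if (anyDuplicated(met_ids))
    problems <- c(problems, paste0("duplicated metabolite ids: ",
      paste(unique(met_ids[duplicated(met_ids)]), collapse = ", ")))
  if (!"phylum" %in% names(x$taxonomy))
    problems <- c(problems, "taxonomy lacks a phylum entry")
  rxn_ids <- names(x$reactions)
  if (anyDuplicated(rxn_ids))
    problems <- c(problems, paste0("duplicated reaction ids: ",
      paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", ")))
  dangling <- character()
  for (r in x$reactions) {
    if (length(r$stoich) == 0L)
      problems <- c(problems, paste0("reaction ", r$id, " has empty stoichiometry"))
    if (any(!is.finite(r$stoich)) || any(r$stoich == 0))
      problems <- c(problems,
        paste0("reaction ", r$id, " has non-finite or zero coefficients"))
    if (!is.finite(r$lb) || !is.finite(r$ub) || r$lb > r$ub)
      problems <- c(problems, paste0("reaction ", r$id, " has invalid bounds"))
    missing <- setdiff(names(r$stoich), met_ids)
    if (length(missing)) dangling <- c(dangling, missing)
  }
  if (length(dangling))
    problems <- c(problems, paste0("stoichiometry references undeclared metabolites: ",
      paste(sort(unique(dangling)), collapse = ", ")))
  if (!x$biomass_reaction %in% rxn_ids)
    problems <- c(problems,
      paste0("biomass reaction ", x$biomass_reaction, " not found"))
  for (ex in x$exchanges) {
    if (!ex %in% rxn_ids) {
      problems <- c(problems, paste0("exchange ", ex, " not found"))
    } else if (length(x$reactions[[ex]]$stoich) != 1L) {
      problems <- c(problems,
        paste0("exchange ", ex, " must involve exactly one metabolite"))
    }
  }
  if (length(problems))
    stop("invalid GEM '", x$id, "':\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  invisible(x)
}

#' @export
print.gem <- function(x, ...) {
  cat("<gem> ", x$id, "\n",
      "  taxonomy:    ", paste(names(x$taxonomy), x$taxonomy, sep = "=",
                               collapse = "; "), "\n",
      "  metabolites: ", nrow(x$metabolites), "\n",
      "  reactions:   ", length(x$reactions),
      " (", length(x$exchanges), " exchanges)\n",
      "  biomass:     ", x$biomass_reaction, "\n", sep = "")
  invisible(x)
}

#' Reaction ids of a GEM
#' @param x a `gem`.
#' @return character vector of reaction ids (the set R_i of the model).
#' @export
reaction_ids <- function(x) {
  stopifnot(inherits(x, "gem"))
  names(x$reactions)
}

#' Reactions of a GEM as a tibble
#' @param x a `gem`.
#' @return a tibble with one row per reaction: `reaction_id`, `lb`, `ub`,
#'   `subsystem`, `n_metabolites`, `ko` (list-column).
#' @export
gem_reactions <- function(x) {
  stopifnot(inherits(x, "gem"))
  tibble::tibble(
    reaction_id = names(x$reactions),
    lb = vapply(x$reactions, `[[`, 0, "lb"),
    ub = vapply(x$reactions, `[[`, 0, "ub"),
    subsystem = vapply(x$reactions, function(r) r$subsystem %||% NA_character_, ""),
    n_metabolites = vapply(x$reactions, function(r) length(r$stoich), 0L),
    ko = lapply(x$reactions, `[[`, "ko"))
}

#' Stoichiometric matrix of a GEM
#'
#' @param x a `gem`.
#' @return dense numeric matrix S (metabolites x reactions) with dimnames.
#' @export
stoichiometric_matrix <- function(x) {
  stopifnot(inherits(x, "gem"))
  mets <- x$metabolites$id
  rxns <- names(x$reactions)
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (j in seq_along(rxns)) {
    st <- x$reactions[[j]]$stoich
    S[names(st), j] <- st
  }
  S
}

#' Read a GEM from its JSON representation
#'
#' The dialect has top-level keys `id`, `taxonomy`, `metabolites` (list of
#' `{id, name, compartment, formula?, kegg?}`), `reactions` (list of
#' `{id, stoich: {met_id: coef}, lb, ub, ko?, subsystem?}`),
#' `biomass_reaction` and `exchanges`.
#'
#' @param path path to a JSON model file.
#' @return a validated `gem`.
#' @export
read_gem <- function(path) {
  if (!file.exists(path)) stop("no such model file: ", path)
  raw <- jsonlite::read_json(path)
  for (key in c("id", "metabolites", "reactions", "biomass_reaction", "exchanges")) {
    if (is.null(raw[[key]]))
      stop("model file ", path, " is missing required field '", key, "'")
  }
  mets <- purrr::map_dfr(raw$metabolites, function(m) {
    if (is.null(m$id) || is.null(m$compartment))
      stop("model file ", path, ": metabolite entry lacks 'id' or 'compartment'")
    tibble::tibble(id = m$id, name = m$name %||% m$id,
                   compartment = m$compartment,
                   formula = m$formula %||% NA_character_,
                   kegg = m$kegg %||% NA_character_)
  })
  rxns <- lapply(raw$reactions, function(r) {
    if (is.null(r$id) || is.null(r$stoich) || is.null(r$lb) || is.null(r$ub))
      stop("model file ", path, ": reaction entry lacks 'id', 'stoich', 'lb' or 'ub'")
    list(id = r$id, stoich = unlist(r$stoich), lb = r$lb, ub = r$ub,
         ko = unlist(r$ko) %||% character(), subsystem = r$subsystem %||% NA_character_)
  })
  gem(id = raw$id,
      taxonomy = unlist(raw$taxonomy) %||% c(phylum = "unclassified"),
      metabolites = mets,
      reactions = rxns,
      biomass_reaction = raw$biomass_reaction,
      exchanges = unlist(raw$exchanges))
}

#' Write a GEM to the JSON dialect
#'
#' Serialization is canonical (fixed key order, stoichiometry keys sorted) so
#' that a save/load round trip is content-identical.
#'
#' @param x a `gem`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gem <- function(x, path) {
  validate_gem(x)
  mets <- lapply(seq_len(nrow(x$metabolites)), function(i) {
    m <- x$metabolites[i, ]
    out <- list(id = m$id, name = m$name, compartment = m$compartment)
    if (!is.na(m$formula)) out$formula <- m$formula
    if (!is.na(m$kegg)) out$kegg <- m$kegg
    out
  })
  rxns <- lapply(x$reactions, function(r) {
    st <- r$stoich[order(names(r$stoich))]
    out <- list(id = r$id, stoich = as.list(st), lb = r$lb, ub = r$ub)
    if (length(r$ko)) out$ko <- as.list(sort(r$ko))
    if (!is.na(r$subsystem)) out$subsystem <- r$subsystem
    out
  })
  obj <- list(id = x$id,
              taxonomy = as.list(x$taxonomy),
              metabolites = mets,
              reactions = unname(rxns),
              biomass_reaction = x$biomass_reaction,
              exchanges = as.list(x$exchanges))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Reaction presence/absence matrix across models
#'
#' Builds the binary species x reaction matrix over the union of all models'
#' reaction sets; entry (i, j) is 1 iff model i carries reaction j. Columns
#' are ordered lexicographically so the matrix is reproducible.
#'
#' @param gems a list of `gem` objects.
#' @return binary integer matrix with model ids as rownames and reaction ids
#'   as colnames.
#' @export
reaction_presence <- function(gems) {
  stopifnot(length(gems) >= 1L)
  gems <- as_gem_list(gems)
  universe <- sort(unique(unlist(lapply(gems, reaction_ids))))
  P <- matrix(0L, length(gems), length(universe),
              dimnames = list(vapply(gems, `[[`, "", "id"), universe))
  for (i in seq_along(gems)) P[i, reaction_ids(gems[[i]])] <- 1L
  P
}

#' Jaccard distance between the reaction sets of two models
#'
#' `D = 1 - |Ra intersect Rb| / |Ra union Rb|` on reaction-id sets: 0 for
#' models with identical reaction content, 1 for models sharing none.
#' [jaccard_index()] is the complementary similarity `1 - D`.
#'
#' @param gem_a,gem_b `gem` objects (or plain character vectors of reaction
#'   ids).
#' @return a number in \[0, 1\].
#' @export
jaccard_distance <- function(gem_a, gem_b) {
  ra <- if (inherits(gem_a, "gem")) reaction_ids(gem_a) else as.character(gem_a)
  rb <- if (inherits(gem_b, "gem")) reaction_ids(gem_b) else as.character(gem_b)
  ra <- unique(ra); rb <- unique(rb)
  if (length(ra) == 0L && length(rb) == 0L)
    stop("Jaccard distance is undefined for two empty reaction sets")
  1 - length(intersect(ra, rb)) / length(union(ra, rb))
}

#' @rdname jaccard_distance
#' @export
jaccard_index <- function(gem_a, gem_b) 1 - jaccard_distance(gem_a, gem_b)

#' Pairwise Jaccard summary over a set of models
#'
#' @param gems list of `gem` objects.
#' @param type `"distance"` (the default, `D`) or `"index"` (`1 - D`).
#' @return a tibble of model pairs with the requested statistic; the
#'   off-diagonal mean is the usual model-dissimilarity summary.
#' @export
jaccard_pairs <- function(gems, type = c("distance", "index")) {
  type <- match.arg(type)
  gems <- as_gem_list(gems)
  ids <- vapply(gems, `[[`, "", "id")
  pairs <- utils::combn(seq_along(gems), 2)
  value <- apply(pairs, 2, function(p) jaccard_distance(gems[[p[1]]], gems[[p[2]]]))
  if (type == "index") value <- 1 - value
  tibble::tibble(model_a = ids[pairs[1, ]], model_b = ids[pairs[2, ]],
                 statistic = type, value = value)
}

as_gem_list <- function(gems) {
  if (inherits(gems, "gem")) gems <- list(gems)
  stopifnot(all(vapply(gems, inherits, TRUE, "gem")))
  gems
}
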