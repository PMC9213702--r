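#' Pick the top-N most abundant species with available models
#'
#' Community models are built from the N most abundant modelled species of a
#' sample (N = 10 by default, a computational compromise), with relative
#' abundances renormalized over the selection so the weights sum to one.
#' Ties at the cut are broken lexicographically by species id.
#'
#' @param abundance_row named numeric vector of MSP relative abundances for
#'   one sample (or a one-row abundance tibble).
#' @param n number of species to keep (default 10).
#' @param gems_available character vector of MSP ids that have a model.
#' @return a tibble `model_id`, `abundance`, `weight` ordered by decreasing
#'   abundance; weights sum to 1.
#' @export
select_top_n <- function(abundance_row, n = 10, gems_available) {
  if (is.data.frame(abundance_row)) {
    stopifnot(nrow(abundance_row) == 1L)
    abundance_row <- unlist(abundance_row[setdiff(names(abundance_row), "sample_id")])
  }
  a <- abundance_row[names(abundance_row) %in% gems_available & abundance_row > 0]
  if (length(a) == 0L)
    stop("no species with positive abundance and an available model")
  ord <- order(-a, names(a))
  keep <- a[ord][seq_len(min(n, length(a)))]
  tibble::tibble(model_id = names(keep),
                 abundance = unname(keep),
                 weight = unname(keep) / sum(keep))
}

#' Merge species models into a personalized community model
#'
#' Builds one stoichiometric system from several species models and their
#' relative abundances. Each species keeps its internal metabolism in a
#' private cytosol compartment (ids suffixed `_c_<i>`); its exchange
#' reactions are removed and the external metabolites become a shared lumen
#' (`_u`) through which species interact. Every lumen metabolite gets
#' exactly one diet-uptake reaction from the diet side (`_d -> _u`) and one
#' output reaction to the faeces/blood side (`_u -> _f`); the `_d`/`_f`
#' metabolites are boundary species outside the mass balance. Each species'
#' biomass reaction additionally produces a species-biomass metabolite, and
#' one community biomass reaction consumes those at stoichiometric
#' coefficients equal to the abundance weights — so at steady state every
#' species' biomass flux is coupled as `v_bio_i = weight_i * v_community`
#' (equality coupling). `coupling = "bound"` relaxes this to the
#' proportional-bound variant `v_bio_i <= weight_i * 1000` for sensitivity
#' checks.
#'
#' @param gems list of `gem`s sharing one metabolite namespace.
#' @param weights named numeric vector (gem id -> weight), positive,
#'   summing to 1 (tolerance 1e-6).
#' @param coupling `"equality"` (default) or `"bound"`.
#' @return an object of class `community_model`.
#' @export
make_community <- function(gems, weights, coupling = c("equality", "bound")) {
  coupling <- match.arg(coupling)
  gems <- as_gem_list(gems)
  ids <- vapply(gems, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate species ids in community")
  if (!all(ids %in% names(weights))) stop("weights must cover every species")
  weights <- weights[ids]
  if (any(weights <= 0)) stop("weights must be positive")
  if (abs(sum(weights) - 1) > 1e-6)
    stop("weights must sum to 1 (off by ", format(abs(sum(weights) - 1)), ")")

  mets <- list()
  rxns <- list()
  lumen <- character() # lumen met id -> source external id
  biomass_mets <- character(length(gems))
  biomass_rxns <- character(length(gems))
  if (coupling == "bound")
    mets[["biomass_total"]] <- list(id = "biomass_total", compartment = "u",
                                    boundary = FALSE)

  for (i in seq_along(gems)) {
    g <- gems[[i]]
    ex_mets <- vapply(g$exchanges, function(ex) names(g$reactions[[ex]]$stoich), "")
    remap <- ifelse(g$metabolites$id %in% ex_mets,
                    paste0(g$metabolites$id, "_u"),
                    paste0(g$metabolites$id, "_c_", i))
    names(remap) <- g$metabolites$id
    for (k in seq_len(nrow(g$metabolites))) {
      orig <- g$metabolites$id[k]
      newid <- remap[[orig]]
      if (is.null(mets[[newid]]))
        mets[[newid]] <- list(id = newid,
                              compartment = if (orig %in% ex_mets) "u"
                                            else paste0("c_", i),
                              boundary = FALSE)
      if (orig %in% ex_mets && !newid %in% names(lumen)) {
        lumen[newid] <- orig
      }
    }
    bm_met <- if (coupling == "bound") "biomass_total" else
      paste0("biomass_sp_", i)
    if (coupling == "equality")
      mets[[bm_met]] <- list(id = bm_met, compartment = paste0("c_", i),
                             boundary = FALSE)
    biomass_mets[i] <- bm_met
    for (r in g$reactions) {
      if (r$id %in% g$exchanges) next # exchanges are replaced by lumen wiring
      st <- r$stoich
      names(st) <- remap[names(st)]
      rid <- paste0(r$id, "_sp_", i)
      if (r$id == g$biomass_reaction) {
        st <- c(st, stats::setNames(1, bm_met))
        lbub <- c(r$lb, if (coupling == "bound") weights[[i]] * 1000 else r$ub)
        biomass_rxns[i] <- rid
      } else lbub <- c(r$lb, r$ub)
      rxns[[rid]] <- list(id = rid, stoich = st, lb = lbub[1], ub = lbub[2],
                          ko = r$ko, subsystem = r$subsystem,
                          type = "internal", species = g$id)
    }
  }

  # lumen wiring: one diet-uptake and one output reaction per lumen metabolite
  for (lm in names(lumen)) {
    src <- lumen[[lm]]
    dmet <- paste0(src, "_d"); fmet <- paste0(src, "_f")
    mets[[dmet]] <- list(id = dmet, compartment = "d", boundary = TRUE)
    mets[[fmet]] <- list(id = fmet, compartment = "f", boundary = TRUE)
    rxns[[paste0("DIET_", src)]] <- list(
      id = paste0("DIET_", src),
      stoich = stats::setNames(c(-1, 1), c(dmet, lm)),
      lb = 0, ub = 1000, ko = character(), subsystem = NA_character_,
      type = "diet", species = NA_character_, source_metabolite = src)
    rxns[[paste0("OUT_", src)]] <- list(
      id = paste0("OUT_", src),
      stoich = stats::setNames(c(-1, 1), c(lm, fmet)),
      lb = 0, ub = 1000, ko = character(), subsystem = NA_character_,
      type = "output", species = NA_character_, source_metabolite = src)
  }

  comm_bm <- "community_biomass"
  bm_stoich <- if (coupling == "equality")
    stats::setNames(-unname(weights), biomass_mets)
  else c(biomass_total = -1)
  rxns[[comm_bm]] <- list(id = comm_bm, stoich = bm_stoich,
                          lb = 0, ub = 1000, ko = character(),
                          subsystem = NA_character_,
                          type = "community_biomass", species = NA_character_)

  structure(list(
    id = paste0("community_", paste(ids, collapse = "+")),
    species = ids,
    weights = weights,
    coupling = coupling,
    metabolites = purrr::map_dfr(mets, tibble::as_tibble),
    reactions = rxns,
    lumen = tibble::tibble(lumen_id = names(lumen), source_id = unname(lumen)),
    biomass_mets = stats::setNames(biomass_mets, ids),
    biomass_rxns = stats::setNames(biomass_rxns, ids),
    community_biomass_reaction = comm_bm), class = "community_model")
}

#' @export
print.community_model <- function(x, ...) {
  cat("<community_model> ", length(x$species), " species (",
      x$coupling, " coupling)\n",
      "  reactions:   ", length(x$reactions), "\n",
      "  metabolites: ", nrow(x$metabolites),
      " (", nrow(x$lumen), " lumen)\n", sep = "")
  invisible(x)
}

community_stoich <- function(model) {
  keep <- model$metabolites$id[!model$metabolites$boundary]
  rxn_ids <- names(model$reactions)
  S <- matrix(0, length(keep), length(rxn_ids),
              dimnames = list(keep, rxn_ids))
  for (j in seq_along(rxn_ids)) {
    st <- model$reactions[[j]]$stoich
    st <- st[names(st) %in% keep]
    S[names(st), j] <- st
  }
  S
}

#' Community flux balance analysis
#'
#' Applies the diet to the diet-uptake reactions (community-level totals:
#' each lumen metabolite's `DIET_` reaction gets upper bound equal to its
#' diet limit, 0 if absent; anaerobically, oxygen inflow is closed), then
#' maximizes the community biomass flux subject to steady state in every
#' non-boundary compartment, bounds, and the abundance coupling.
#'
#' @param model a `community_model`.
#' @param diet a [diet()] keyed by the external metabolite ids of the
#'   member models.
#' @return an object of class `community_fba_result` with `status`,
#'   `community_growth`, `species_growth` (named by species),
#'   `net_exchange` (tibble: `metabolite_id`, `diet_flux`, `output_flux`,
#'   `net`) and the full `fluxes` vector.
#' @export
community_fba <- function(model, diet) {
  stopifnot(inherits(model, "community_model"), inherits(diet, "diet"))
  for (rid in names(model$reactions)) {
    r <- model$reactions[[rid]]
    if (identical(r$type, "diet")) {
      lim <- diet$uptake_limits[r$source_metabolite]
      ub <- if (!is.na(lim)) as.numeric(lim) else 0
      if (diet$anaerobic && is_oxygen_id(r$source_metabolite)) ub <- 0
      model$reactions[[rid]]$ub <- ub
    }
  }
  S <- community_stoich(model)
  lb <- pmax(vapply(model$reactions, `[[`, 0, "lb"), -1e6)
  ub <- pmin(vapply(model$reactions, `[[`, 0, "ub"), 1e6)
  obj <- as.numeric(colnames(S) == model$community_biomass_reaction)
  sol <- solve_lp(obj, S, lb = lb, ub = ub, maximize = TRUE)
  out <- list(status = sol$status, model_id = model$id,
              species = model$species, weights = model$weights,
              coupling = model$coupling)
  if (sol$status == "optimal") {
    fluxes <- stats::setNames(sol$x, colnames(S))
    out$community_growth <- unname(fluxes[model$community_biomass_reaction])
    out$species_growth <- stats::setNames(
      unname(fluxes[model$biomass_rxns]), model$species)
    dietf <- stats::setNames(fluxes[paste0("DIET_", model$lumen$source_id)],
                             model$lumen$source_id)
    outf <- stats::setNames(fluxes[paste0("OUT_", model$lumen$source_id)],
                            model$lumen$source_id)
    out$net_exchange <- tibble::tibble(
      metabolite_id = model$lumen$source_id,
      diet_flux = unname(dietf),
      output_flux = unname(outf),
      net = unname(outf - dietf))
    out$fluxes <- fluxes
    out$balance_violation <- max(abs(S %*% sol$x))
  } else {
    out$community_growth <- NA_real_
  }
  structure(out, class = "community_fba_result")
}

#' @export
print.community_fba_result <- function(x, ...) {
  cat("<community_fba_result> ", x$model_id, ": ", x$status, sep = "")
  if (x$status == "optimal")
    cat(", community growth ", format(x$community_growth, digits = 6), sep = "")
  cat("\n")
  invisible(x)
}

#' @export
tidy.community_fba_result <- function(x, ...) {
  if (x$status != "optimal")
    return(tibble::tibble(reaction_id = character(), flux = numeric()))
  tibble::tibble(reaction_id = names(x$fluxes), flux = unname(x$fluxes))
}

#' @export
glance.community_fba_result <- function(x, ...) {
  tibble::tibble(model_id = x$model_id, status = x$status,
                 community_growth = x$community_growth,
                 n_species = length(x$species),
                 coupling = x$coupling)
}

#' Net exchange profile of a community simulation
#'
#' Classifies each lumen metabolite by its net flow through the system:
#' positive net (output to faeces/blood exceeding diet inflow) means the
#' community produces it, negative net means it consumes diet supply.
#'
#' @param result an optimal `community_fba_result`.
#' @param eps classification tolerance (default 1e-6).
#' @return tibble `metabolite_id`, `diet_flux`, `output_flux`, `net`,
#'   `class`.
#' @export
net_exchange_profile <- function(result, eps = 1e-6) {
  stopifnot(inherits(result, "community_fba_result"))
  if (result$status != "optimal")
    stop("net_exchange_profile() needs an optimal community FBA result")
  dplyr::mutate(result$net_exchange,
                class = dplyr::case_when(.data$net > eps ~ "produced",
                                         .data$net < -eps ~ "consumed",
                                         TRUE ~ "none"))
}
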