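#' Constrain a model's exchange bounds with a diet
#'
#' For each exchange reaction of metabolite `m`, the lower bound becomes
#' `-uptake_limits[m]` when `m` is in the diet and 0 otherwise, so nothing
#' outside the diet can be consumed. Upper (secretion) bounds are left
#' untouched. Under `anaerobic` conditions the oxygen exchange lower bound
#' is forced to 0 even if the diet lists oxygen (the anaerobic flag takes
#' precedence).
#'
#' @param gem a `gem`.
#' @param diet a [diet()].
#' @param warn_missing warn about diet metabolites with no exchange in this
#'   model (diets are usually supersets of any one model's exchanges).
#' @return the bounded `gem`.
#' @export
apply_diet <- function(gem, diet, warn_missing = FALSE) {
  stopifnot(inherits(gem, "gem"), inherits(diet, "diet"))
  seen <- character()
  for (ex in gem$exchanges) {
    met <- names(gem$reactions[[ex]]$stoich)
    lim <- diet$uptake_limits[met]
    gem$reactions[[ex]]$lb <- if (!is.na(lim)) -as.numeric(lim) else 0
    if (diet$anaerobic && is_oxygen_id(met)) gem$reactions[[ex]]$lb <- 0
    seen <- c(seen, met)
  }
  if (warn_missing) {
    missing <- setdiff(names(diet$uptake_limits), seen)
    if (length(missing))
      warning("diet metabolites with no exchange in model ", gem$id, ": ",
              paste(missing, collapse = ", "), call. = FALSE)
  }
  gem
}

is_oxygen_id <- function(met_id) grepl("^o2([_.]|$)", met_id)

#' Flux balance analysis of a single model
#'
#' Maximizes the flux through an objective reaction (by default biomass)
#' subject to steady state `S v = 0` and the reaction bounds, using the
#' package's bounded-variable simplex ([solve_lp()]). The optimum is a
#' vertex of the flux polytope; the objective value is unique but the flux
#' vector need not be.
#'
#' @param gem a `gem`.
#' @param diet optional [diet()]; when supplied, [apply_diet()] is called
#'   first.
#' @param objective objective reaction id (default the model's biomass
#'   reaction, so the objective value is the growth rate in 1/h).
#' @return an object of class `fba_result`: `status` (`"optimal"`,
#'   `"infeasible"` or `"unbounded"`), `growth_rate` (objective flux),
#'   `fluxes` (named vector) and `model_id`. Use [tidy()] for a tibble of
#'   fluxes.
#' @export
fba <- function(gem, diet = NULL, objective = NULL) {
  stopifnot(inherits(gem, "gem"))
  if (!is.null(diet)) gem <- apply_diet(gem, diet)
  objective <- objective %||% gem$biomass_reaction
  if (!objective %in% names(gem$reactions))
    stop("objective reaction ", objective, " not in model ", gem$id)
  S <- stoichiometric_matrix(gem)
  lb <- vapply(gem$reactions, `[[`, 0, "lb")
  ub <- vapply(gem$reactions, `[[`, 0, "ub")
  lb <- pmax(lb, -1e6)
  ub <- pmin(ub, 1e6)
  obj <- as.numeric(colnames(S) == objective)
  sol <- solve_lp(obj, S, lb = lb, ub = ub, maximize = TRUE)
  res <- list(status = sol$status, model_id = gem$id, objective_id = objective)
  if (sol$status == "optimal") {
    fluxes <- stats::setNames(sol$x, colnames(S))
    res$growth_rate <- unname(fluxes[objective])
    res$fluxes <- fluxes
    res$balance_violation <- max(abs(S %*% sol$x))
  } else {
    res$growth_rate <- NA_real_
    res$fluxes <- NULL
    res$balance_violation <- NA_real_
  }
  structure(res, class = "fba_result")
}

#' @export
print.fba_result <- function(x, ...) {
  cat("<fba_result> model ", x$model_id, ": ", x$status, sep = "")
  if (x$status == "optimal")
    cat(", growth ", format(x$growth_rate, digits = 6), " (objective ",
        x$objective_id, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
tidy.fba_result <- function(x, ...) {
  if (x$status != "optimal")
    return(tibble::tibble(reaction_id = character(), flux = numeric()))
  tibble::tibble(reaction_id = names(x$fluxes), flux = unname(x$fluxes))
}

#' @export
glance.fba_result <- function(x, ...) {
  tibble::tibble(model_id = x$model_id, status = x$status,
                 growth_rate = x$growth_rate,
                 n_reactions = length(x$fluxes),
                 balance_violation = x$balance_violation)
}

#' Classify exchange fluxes into produced / consumed metabolites
#'
#' Follows the usual sign convention: negative exchange flux means the model
#' takes the metabolite up, positive means it secretes it. Fluxes within
#' `eps` of zero are classified as neither.
#'
#' @param gem the `gem` that was simulated.
#' @param result an optimal `fba_result` for it.
#' @param eps classification tolerance (default 1e-6 mmol/gDW/h).
#' @return a tibble with `metabolite_id`, `reaction_id`, `flux` and `class`
#'   in `c("produced", "consumed", "none")`.
#' @export
exchange_profile <- function(gem, result, eps = 1e-6) {
  stopifnot(inherits(gem, "gem"), inherits(result, "fba_result"))
  if (result$status != "optimal")
    stop("exchange_profile() needs an optimal FBA result")
  stopifnot(eps > 0)
  mets <- vapply(gem$exchanges, function(ex) names(gem$reactions[[ex]]$stoich), "")
  flux <- unname(result$fluxes[gem$exchanges])
  tibble::tibble(
    metabolite_id = unname(mets),
    reaction_id = gem$exchanges,
    flux = flux,
    class = dplyr::case_when(flux > eps ~ "produced",
                             flux < -eps ~ "consumed",
                             TRUE ~ "none"))
}

#' Average exchange flux per metabolite within model groups
#'
#' Compares the mean exchange flux of metabolites between groups of models
#' (typically disease-enriched vs control-enriched species). By default a
#' model lacking an exchange for a metabolite contributes flux 0, keeping
#' group means comparable across the shared metabolite panel; set
#' `carriers_only = TRUE` to average only over models that carry the
#' exchange.
#'
#' @param profiles a tibble binding exchange profiles of several models,
#'   with columns `model_id`, `metabolite_id`, `flux` (see
#'   [exchange_profile()]).
#' @param groups a tibble with columns `model_id`, `group`.
#' @param carriers_only average only over models carrying the exchange.
#' @return a tibble `metabolite_id`, `group`, `mean_flux`, `n_models`.
#' @export
group_average_flux <- function(profiles, groups, carriers_only = FALSE) {
  stopifnot(all(c("model_id", "metabolite_id", "flux") %in% names(profiles)),
            all(c("model_id", "group") %in% names(groups)))
  if (nrow(groups) == 0L || dplyr::n_distinct(groups$group) < 1L)
    stop("no model groups supplied")
  joined <- dplyr::inner_join(profiles, groups, by = "model_id")
  missing_groups <- setdiff(groups$group, joined$group)
  if (length(missing_groups))
    stop("group(s) with no profiled models: ",
         paste(missing_groups, collapse = ", "))
  if (!carriers_only) {
    grid <- tidyr::expand_grid(
      dplyr::distinct(joined[, c("model_id", "group")]),
      metabolite_id = unique(profiles$metabolite_id))
    joined <- grid |>
      dplyr::left_join(joined[, c("model_id", "group", "metabolite_id", "flux")],
                       by = c("model_id", "group", "metabolite_id")) |>
      tidyr::replace_na(list(flux = 0))
  }
  joined |>
    dplyr::group_by(.data$group, .data$metabolite_id) |>
    dplyr::summarise(mean_flux = mean(.data$flux), n_models = dplyr::n(),
                     .groups = "drop")
}

#' Check that a model is functional (can grow) on a rich medium
#'
#' A functional model produces biomass when every uptake is open. When
#' growth fails, the report names the biomass precursors that cannot be
#' synthesised (tested one at a time with a temporary sink).
#'
#' @param gem a `gem`.
#' @param rich_medium a [diet()] opening every exchange; by default one is
#'   built from the model's own exchange metabolites at uptake 1000,
#'   aerobically.
#' @param tol growth threshold for calling the model functional.
#' @return a list with `functional` (logical), `growth_rate`, and `blocked`
#'   (character vector of unproducible biomass precursors, empty when
#'   functional).
#' @export
validate_functional <- function(gem, rich_medium = NULL, tol = 1e-6) {
  stopifnot(inherits(gem, "gem"))
  if (is.null(gem$biomass_reaction) || !gem$biomass_reaction %in% names(gem$reactions))
    stop("model ", gem$id, " has no biomass reaction")
  if (is.null(rich_medium)) {
    mets <- vapply(gem$exchanges, function(ex) names(gem$reactions[[ex]]$stoich), "")
    rich_medium <- diet(stats::setNames(rep(1000, length(mets)), mets),
                        anaerobic = FALSE)
  }
  bounded <- apply_diet(gem, rich_medium)
  res <- fba(bounded)
  growth <- if (res$status == "optimal") res$growth_rate else 0
  if (res$status == "optimal" && growth > tol)
    return(list(functional = TRUE, growth_rate = growth, blocked = character()))

  # identify blocked biomass precursors with one-at-a-time sink maximization
  S <- stoichiometric_matrix(bounded)
  lb <- pmax(vapply(bounded$reactions, `[[`, 0, "lb"), -1e6)
  ub <- pmin(vapply(bounded$reactions, `[[`, 0, "ub"), 1e6)
  bm <- bounded$reactions[[bounded$biomass_reaction]]$stoich
  precursors <- names(bm)[bm < 0]
  blocked <- character()
  for (m in precursors) {
    sink <- as.numeric(rownames(S) == m) * -1
    S2 <- cbind(S, sink)
    sol <- solve_lp(c(rep(0, ncol(S)), 1), S2,
                    lb = c(lb, 0), ub = c(ub, 1000), maximize = TRUE)
    if (sol$status != "optimal" || sol$objective < tol) blocked <- c(blocked, m)
  }
  list(functional = FALSE, growth_rate = growth, blocked = blocked)
}
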