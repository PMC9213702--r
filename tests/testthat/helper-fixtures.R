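# Tiny deterministic models used across the tests.

# Linear chain: uptake A (cap 10) -> transport -> conversion -> biomass.
# Optimal growth = 10 * yield.
chain_gem <- function(id = "chain", yield = 1) {
  gem(
    id = id,
    taxonomy = c(phylum = "Firmicutes"),
    metabolites = tibble::tibble(
      id = c("A_e", "A_c", "B_c"),
      name = c("substrate A", "substrate A", "precursor B"),
      compartment = c("e", "c", "c")),
    reactions = list(
      list(id = "EX_A", stoich = c(A_e = -1), lb = -10, ub = 1000),
      list(id = "T_A", stoich = c(A_e = -1, A_c = 1), lb = 0, ub = 1000),
      list(id = "CONV", stoich = c(A_c = -1, B_c = yield), lb = 0, ub = 1000),
      list(id = "BIOMASS", stoich = c(B_c = -1), lb = 0, ub = 1000)),
    biomass_reaction = "BIOMASS",
    exchanges = "EX_A")
}

# Branched toy network: two substrates with different yields and a capped
# internal route, small enough for vertex enumeration.
branched_gem <- function(id = "branched") {
  gem(
    id = id,
    taxonomy = c(phylum = "Bacteroidetes"),
    metabolites = tibble::tibble(
      id = c("A_e", "B_e", "A_c", "B_c", "P_c"),
      name = c("A", "B", "A", "B", "precursor"),
      compartment = c("e", "e", "c", "c", "c")),
    reactions = list(
      list(id = "EX_A", stoich = c(A_e = -1), lb = -5, ub = 1000),
      list(id = "EX_B", stoich = c(B_e = -1), lb = -4, ub = 1000),
      list(id = "T_A", stoich = c(A_e = -1, A_c = 1), lb = 0, ub = 1000),
      list(id = "T_B", stoich = c(B_e = -1, B_c = 1), lb = 0, ub = 3),
      list(id = "RA", stoich = c(A_c = -1, P_c = 1), lb = 0, ub = 1000),
      list(id = "RB", stoich = c(B_c = -1, P_c = 2), lb = 0, ub = 1000),
      list(id = "BIOMASS", stoich = c(P_c = -1), lb = 0, ub = 1000)),
    biomass_reaction = "BIOMASS",
    exchanges = c("EX_A", "EX_B"))
}

# a GEM with an arbitrary reaction-id set, for set-based operations
idset_gem <- function(id, rxn_ids) {
  mets <- tibble::tibble(id = "m_c", name = "m", compartment = "c")
  rxns <- c(
    lapply(rxn_ids, function(r)
      list(id = r, stoich = c(m_c = 1), lb = 0, ub = 1000)),
    list(list(id = paste0("BM_", id), stoich = c(m_c = -1), lb = 0, ub = 1000)))
  gem(id = id, taxonomy = c(phylum = "Firmicutes"),
      metabolites = mets, reactions = rxns,
      biomass_reaction = paste0("BM_", id), exchanges = character())
}

small_config <- function(seed = 11, ...) {
  synthetic_config(n_species = 16, n_samples_case = 20, n_samples_control = 20,
                   n_planted_differential = 6, n_samples_wellness = 40,
                   n_metabolites = 40, n_planted_associations = 4,
                   seed = seed, ...)
}
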