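test_that("top-N selection renormalizes, tie-breaks and truncates correctly", {
  sel <- select_top_n(c(A = 0.5, B = 0.3, C = 0.2), n = 2,
                      gems_available = c("A", "B", "C"))
  expect_equal(sel$model_id, c("A", "B"))
  expect_equal(sel$weight, c(0.625, 0.375))
  # n beyond the species count keeps everything
  sel2 <- select_top_n(c(A = 0.5, B = 0.5), n = 10,
                       gems_available = c("A", "B"))
  expect_equal(nrow(sel2), 2L)
  expect_equal(sum(sel2$weight), 1)
  # tie at the cut goes to the lexicographically smaller id
  sel3 <- select_top_n(c(mspB = 0.2, mspA = 0.2, mspC = 0.6), n = 2,
                       gems_available = c("mspA", "mspB", "mspC"))
  expect_equal(sort(sel3$model_id), c("mspA", "mspC"))
  # species without models are ignored
  sel4 <- select_top_n(c(A = 0.9, B = 0.1), n = 2, gems_available = "B")
  expect_equal(sel4$model_id, "B")
  expect_error(select_top_n(c(A = 0), n = 2, gems_available = "A"),
               "positive abundance")
})

test_that("community construction counts and lumen wiring are as designed", {
  g <- chain_gem()
  cm <- make_community(list(g), c(chain = 1))
  # species reactions minus its exchange, + 2 per lumen metabolite,
  # + community biomass
  n_lumen <- nrow(cm$lumen)
  expect_equal(n_lumen, 1L)
  expect_equal(length(cm$reactions),
               (length(g$reactions) - length(g$exchanges)) + 2 * n_lumen + 1)

  # two species sharing a lumen metabolite: wiring is deduplicated
  g2 <- chain_gem(id = "chain2")
  cm2 <- make_community(list(g, g2), c(chain = 0.5, chain2 = 0.5))
  expect_equal(nrow(cm2$lumen), 1L)
  expect_length(grep("^DIET_", names(cm2$reactions)), 1L)
  expect_length(grep("^OUT_", names(cm2$reactions)), 1L)

  expect_error(make_community(list(g, g), c(chain = 0.5)), "duplicate")
  expect_error(make_community(list(g), c(chain = 0.9)), "sum to 1")
})

test_that("merged stoichiometry equals an explicit block assembly for two species", {
  ga <- chain_gem(id = "spA", yield = 1)
  gb <- chain_gem(id = "spB", yield = 2)
  cm <- make_community(list(ga, gb), c(spA = 0.5, spB = 0.5))
  S <- gutflux:::community_stoich(cm)

  # expected rows: lumen A_e_u; per species A_c, B_c, biomass met
  expect_setequal(rownames(S),
                  c("A_e_u", "A_c_c_1", "B_c_c_1", "biomass_sp_1",
                    "A_c_c_2", "B_c_c_2", "biomass_sp_2"))
  # transport of species 1 consumes the shared lumen metabolite
  expect_equal(S["A_e_u", "T_A_sp_1"], -1)
  expect_equal(S["A_c_c_1", "T_A_sp_1"], 1)
  # species blocks do not cross: species-1 rows have zero coefficients in
  # species-2 columns
  sp2_cols <- grep("_sp_2$", colnames(S), value = TRUE)
  expect_true(all(S[c("A_c_c_1", "B_c_c_1", "biomass_sp_1"), sp2_cols] == 0))
  # diet and output wiring on the lumen row
  expect_equal(S["A_e_u", "DIET_A_e"], 1)
  expect_equal(S["A_e_u", "OUT_A_e"], -1)
  # community biomass consumes the species biomass metabolites at weights
  expect_equal(S["biomass_sp_1", "community_biomass"], -0.5)
  expect_equal(S["biomass_sp_2", "community_biomass"], -0.5)
  # species biomass reactions produce their biomass metabolite
  expect_equal(S["biomass_sp_1", "BIOMASS_sp_1"], 1)
})

test_that("a single-species community reproduces single-model FBA", {
  d <- high_fibre_diet()
  cfg <- small_config(seed = 9)
  gems <- generate_toy_gems(cfg)$gems
  for (g in gems[1:6]) {
    single <- fba(g, d)
    cm <- make_community(list(g), stats::setNames(1, g$id))
    comm <- community_fba(cm, d)
    expect_equal(comm$status, "optimal")
    expect_equal(comm$community_growth, single$growth_rate, tolerance = 1e-6)
    expect_equal(unname(comm$species_growth[g$id]), single$growth_rate,
                 tolerance = 1e-6)
  }
})

test_that("two identical species sharing a capped substrate split it evenly", {
  ga <- chain_gem(id = "twinA")
  gb <- chain_gem(id = "twinB")
  cm <- make_community(list(ga, gb), c(twinA = 0.5, twinB = 0.5))
  d <- diet(c(A_e = 10), anaerobic = FALSE)
  res <- community_fba(cm, d)
  # yield 1, total substrate 10 -> community growth 10, each twin 5
  expect_equal(res$community_growth, 10, tolerance = 1e-6)
  expect_equal(unname(res$species_growth), c(5, 5), tolerance = 1e-6)
  expect_lt(res$balance_violation, 1e-6)
  # equality coupling: species growth = weight * community growth
  expect_equal(unname(res$species_growth),
               unname(res$weights) * res$community_growth, tolerance = 1e-6)
})

test_that("lumen mass balance holds and coupling only restricts the optimum", {
  d <- high_fibre_diet()
  cfg <- small_config(seed = 10)
  gems <- generate_toy_gems(cfg)$gems[1:3]
  w <- c(0.5, 0.3, 0.2)
  names(w) <- vapply(gems, `[[`, "", "id")
  cm <- make_community(gems, w)
  res <- community_fba(cm, d)
  expect_equal(res$status, "optimal")
  S <- gutflux:::community_stoich(cm)
  lumen_rows <- intersect(cm$lumen$lumen_id, rownames(S))
  expect_lt(max(abs(S[lumen_rows, ] %*% res$fluxes)), 1e-6)

  # the proportional-bound relaxation can only do at least as well
  cm_relaxed <- make_community(gems, w, coupling = "bound")
  res_rel <- community_fba(cm_relaxed, d)
  expect_gte(res_rel$community_growth, res$community_growth - 1e-6)
})

test_that("diet relaxation monotonicity and determinism hold for communities", {
  cfg <- small_config(seed = 12)
  gems <- generate_toy_gems(cfg)$gems[1:3]
  w <- c(0.4, 0.35, 0.25)
  names(w) <- vapply(gems, `[[`, "", "id")
  cm <- make_community(gems, w)
  base <- high_fibre_diet()
  g0 <- community_fba(cm, base)$community_growth
  expect_equal(community_fba(cm, base)$community_growth, g0, tolerance = 1e-9)
  set.seed(4)
  for (k in 1:5) {
    relaxed <- base
    pick <- sample(names(relaxed$uptake_limits), 1)
    relaxed$uptake_limits[pick] <- relaxed$uptake_limits[pick] * runif(1, 1, 2)
    expect_gte(community_fba(cm, relaxed)$community_growth, g0 - 1e-7)
  }
})

test_that("net exchange classifies produced and consumed lumen metabolites", {
  g <- chain_gem()
  cm <- make_community(list(g), c(chain = 1))
  res <- community_fba(cm, diet(c(A_e = 10), anaerobic = FALSE))
  prof <- net_exchange_profile(res)
  expect_equal(prof$class[prof$metabolite_id == "A_e"], "consumed")
  expect_equal(prof$net[prof$metabolite_id == "A_e"], -10, tolerance = 1e-6)
  # with nothing in the diet nothing can be produced or consumed
  res0 <- community_fba(cm, diet(c(none = 1), anaerobic = FALSE))
  prof0 <- net_exchange_profile(res0)
  expect_true(all(prof0$class == "none"))
})
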