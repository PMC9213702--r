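test_that("diet application sets exchange bounds by the stated rule", {
  g <- chain_gem()
  d <- diet(c(A_e = 7, zzz_e = 3), anaerobic = FALSE)
  b <- apply_diet(g, d)
  expect_equal(b$reactions$EX_A$lb, -7)
  expect_equal(b$reactions$EX_A$ub, 1000)
  # metabolite not in diet: uptake closed
  b2 <- apply_diet(g, diet(c(other_e = 5), anaerobic = FALSE))
  expect_equal(b2$reactions$EX_A$lb, 0)
  expect_warning(apply_diet(g, d, warn_missing = TRUE), "zzz_e")
})

test_that("anaerobic flag overrides an oxygen diet entry", {
  g <- gem(id = "aero", taxonomy = c(phylum = "Proteobacteria"),
           metabolites = tibble::tibble(id = c("o2_e", "A_e", "P_c"),
                                        name = c("oxygen", "A", "P"),
                                        compartment = c("e", "e", "c")),
           reactions = list(
             list(id = "EX_o2", stoich = c(o2_e = -1), lb = -1000, ub = 1000),
             list(id = "EX_A", stoich = c(A_e = -1), lb = -1000, ub = 1000),
             list(id = "RESP", stoich = c(o2_e = -1, A_e = -1, P_c = 1),
                  lb = 0, ub = 1000),
             list(id = "BIOMASS", stoich = c(P_c = -1), lb = 0, ub = 1000)),
           biomass_reaction = "BIOMASS", exchanges = c("EX_o2", "EX_A"))
  d <- diet(c(o2_e = 10, A_e = 10), anaerobic = TRUE)
  b <- apply_diet(g, d)
  expect_equal(b$reactions$EX_o2$lb, 0)
  expect_equal(b$reactions$EX_A$lb, -10)
  # and the obligate-aerobic toy cannot grow anaerobically
  expect_lt(fba(g, d)$growth_rate, 1e-9)
  expect_gt(fba(g, diet(c(o2_e = 10, A_e = 10), anaerobic = FALSE))$growth_rate, 1)
})

test_that("chain model growth scales with uptake bound and stoichiometric yield", {
  d <- diet(c(A_e = 10), anaerobic = FALSE)
  expect_equal(fba(chain_gem(yield = 1), d)$growth_rate, 10, tolerance = 1e-9)
  expect_equal(fba(chain_gem(yield = 2), d)$growth_rate, 20, tolerance = 1e-9)
})

test_that("branched network objective matches vertex enumeration", {
  g <- branched_gem()
  d <- diet(c(A_e = 5, B_e = 4), anaerobic = FALSE)
  res <- fba(g, d)
  bounded <- apply_diet(g, d)
  S <- stoichiometric_matrix(bounded)
  lb <- vapply(bounded$reactions, `[[`, 0, "lb")
  ub <- pmin(vapply(bounded$reactions, `[[`, 0, "ub"), 50) # keep vertices small
  oracle <- lp_vertex_oracle(as.numeric(colnames(S) == "BIOMASS"), S,
                             lb = lb, ub = ub)
  # hand check: A route gives 5, B route min(4, cap 3) * 2 = 6 -> 11
  expect_equal(res$growth_rate, 11, tolerance = 1e-6)
  expect_equal(res$growth_rate, oracle$objective, tolerance = 1e-6)
  expect_lt(res$balance_violation, 1e-6)
})

test_that("relaxing a diet uptake limit never decreases growth", {
  cfg <- small_config(seed = 5)
  gems <- generate_toy_gems(cfg)$gems[1:4]
  base <- high_fibre_diet()
  set.seed(99)
  for (g in gems) {
    g0 <- fba(g, base)$growth_rate
    for (k in 1:6) {
      relaxed <- base
      pick <- sample(names(relaxed$uptake_limits), 1)
      relaxed$uptake_limits[pick] <- relaxed$uptake_limits[pick] * runif(1, 1, 3)
      expect_gte(fba(g, relaxed)$growth_rate, g0 - 1e-7)
    }
  }
})

test_that("exchange profile partitions produced and consumed disjointly", {
  g <- chain_gem()
  res <- fba(g, diet(c(A_e = 10), anaerobic = FALSE))
  prof <- exchange_profile(g, res)
  expect_equal(prof$class[prof$metabolite_id == "A_e"], "consumed")
  expect_equal(prof$flux[prof$metabolite_id == "A_e"], -10, tolerance = 1e-9)
  expect_length(intersect(prof$metabolite_id[prof$class == "produced"],
                          prof$metabolite_id[prof$class == "consumed"]), 0)
  # zero flux is neither
  prof0 <- exchange_profile(g, fba(g, diet(c(none = 1), anaerobic = FALSE)))
  expect_equal(prof0$class[prof0$metabolite_id == "A_e"], "none")
})

test_that("group averages use zero for absent exchanges and preserve sign", {
  profiles <- tibble::tibble(
    model_id = c("m1", "m2", "m3", "m4"),
    metabolite_id = c("ac_e", "ac_e", "ac_e", "but_e"),
    flux = c(2, 4, -1, 1))
  groups <- tibble::tibble(model_id = c("m1", "m2", "m3", "m4"),
                           group = c("disease-enriched", "disease-enriched",
                                     "control-enriched", "control-enriched"))
  avg <- group_average_flux(profiles, groups)
  get <- function(met, grp) avg$mean_flux[avg$metabolite_id == met &
                                            avg$group == grp]
  expect_equal(get("ac_e", "disease-enriched"), 3)
  expect_equal(get("ac_e", "control-enriched"), -0.5) # m4 contributes 0
  expect_equal(get("but_e", "control-enriched"), 0.5)
  expect_equal(get("but_e", "disease-enriched"), 0)
  carriers <- group_average_flux(profiles, groups, carriers_only = TRUE)
  expect_equal(carriers$mean_flux[carriers$metabolite_id == "ac_e" &
                                    carriers$group == "control-enriched"], -1)
  expect_error(group_average_flux(profiles,
                                  tibble::tibble(model_id = "zz", group = "g")),
               "group")
})

test_that("functional validation passes growing models and names blocked precursors", {
  g <- chain_gem()
  v <- validate_functional(g)
  expect_true(v$functional)
  expect_gt(v$growth_rate, 0)
  # delete the conversion producing the biomass precursor
  g2 <- g
  g2$reactions$CONV <- NULL
  g2 <- gem(id = g2$id, taxonomy = g2$taxonomy, metabolites = g2$metabolites,
            reactions = g2$reactions, biomass_reaction = "BIOMASS",
            exchanges = "EX_A")
  v2 <- validate_functional(g2)
  expect_false(v2$functional)
  expect_true("B_c" %in% v2$blocked)
})
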