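test_that("reaction abundance is the abundance-weighted presence sum", {
  P <- rbind(MSP1 = c(rA = 1, rB = 1), MSP2 = c(rA = 0, rB = 1))
  ab <- tibble::tibble(sample_id = "s1", MSP1 = 0.3, MSP2 = 0.2)
  ra <- compute_reaction_abundance(P, ab)
  expect_equal(ra$rA, 0.3)
  expect_equal(ra$rB, 0.5)

  ab0 <- tibble::tibble(sample_id = c("s1", "s2"),
                        MSP1 = c(0.3, 0), MSP2 = c(0.2, 0))
  ra0 <- compute_reaction_abundance(P, ab0)
  expect_equal(unlist(ra0[2, c("rA", "rB")]), c(rA = 0, rB = 0))

  expect_error(
    suppressWarnings(
      compute_reaction_abundance(P, tibble::tibble(sample_id = "s1", other = 1))),
    "no overlap")
  expect_warning(
    compute_reaction_abundance(P, tibble::tibble(sample_id = "s1", MSP1 = 0.2)),
    "MSP2")
})

test_that("matrix product equals the explicit triple loop on random instances", {
  set.seed(50)
  for (k in 1:10) {
    ns <- sample(4:8, 1); nr <- sample(10:30, 1); nsmp <- sample(3:6, 1)
    P <- matrix(rbinom(ns * nr, 1, 0.4), ns, nr,
                dimnames = list(sprintf("sp%d", 1:ns), sprintf("r%02d", 1:nr)))
    A <- matrix(runif(nsmp * ns), nsmp, ns,
                dimnames = list(sprintf("s%d", 1:nsmp), rownames(P)))
    ra <- table_to_matrix(compute_reaction_abundance(P, A))
    expect_equal(ra[, colnames(P)], reaction_abundance_loop_oracle(P, A))
  }
})

test_that("reaction abundance is linear and additive in sample abundances", {
  set.seed(51)
  P <- matrix(rbinom(5 * 12, 1, 0.5), 5, 12,
              dimnames = list(sprintf("sp%d", 1:5), sprintf("r%02d", 1:12)))
  A <- matrix(runif(2 * 5), 2, 5, dimnames = list(c("s1", "s2"), rownames(P)))
  ra <- table_to_matrix(compute_reaction_abundance(P, A))
  # scaling a sample scales its row exactly
  ra3 <- table_to_matrix(compute_reaction_abundance(P, A * 3))
  expect_identical(ra3, ra * 3)
  # a mixture sample equals the weighted sum of rows
  mix <- rbind(A, s_mix = 0.25 * A["s1", ] + 0.75 * A["s2", ])
  ram <- table_to_matrix(compute_reaction_abundance(P, mix))
  expect_equal(ram["s_mix", ], 0.25 * ra["s1", ] + 0.75 * ra["s2", ])
  # a reaction carried by no species stays zero
  P0 <- cbind(P, r_none = 0)
  ra0 <- table_to_matrix(compute_reaction_abundance(P0, A))
  expect_true(all(ra0[, "r_none"] == 0))
})

test_that("constant reaction columns are non-significant", {
  set.seed(52)
  m <- cbind(const = rep(0.4, 20), vary = runif(20))
  rownames(m) <- sprintf("s%02d", 1:20)
  meta <- tibble::tibble(sample_id = rownames(m),
                         group = rep(c("case", "control"), each = 10))
  res <- differential_reactions(m, meta)
  expect_equal(res$p_value[res$feature_id == "const"], 1)
})

test_that("cross-disease intersection and direction-consistency filters", {
  mk <- function(ids, fdrs, dirs) tibble::tibble(
    feature_id = ids, fdr = fdrs, direction = dirs)
  per <- list(
    d1 = mk(c("a", "b", "c"), c(0.001, 0.001, 0.001),
            c("disease-enriched", "disease-enriched", "disease-enriched")),
    d2 = mk(c("a", "b", "c"), c(0.5, 0.001, 0.001),
            c("disease-enriched", "control-enriched", "disease-enriched")),
    d3 = mk(c("a", "b", "c"), c(0.001, 0.001, 0.001),
            c("disease-enriched", "disease-enriched", "disease-enriched")))
  shared <- intersect_significant(per)
  expect_equal(shared, c("b", "c"))
  expect_equal(consistent_direction(per, shared), "c")
  # empty overlap is fine
  per2 <- list(d1 = mk("x", 0.001, "disease-enriched"),
               d2 = mk("y", 0.001, "disease-enriched"))
  expect_length(intersect_significant(per2), 0)
})

test_that("KO mapping unions annotations and reports unmapped reactions", {
  komap <- tibble::tibble(reaction_id = c("r1", "r2", "r3"),
                          ko = list("K1", c("K1", "K2"), character()))
  out <- map_to_kos(c("r1", "r2"), komap)
  expect_equal(out$kos, c("K1", "K2"))
  expect_length(out$unmapped, 0)
  out2 <- map_to_kos(c("r3", "r9"), komap)
  expect_length(out2$kos, 0)
  expect_equal(out2$unmapped, c("r3", "r9"))

  # random instance vs brute-force union
  set.seed(60)
  ids <- sprintf("r%02d", 1:20)
  komap_r <- tibble::tibble(
    reaction_id = ids,
    ko = lapply(1:20, function(i) sample(paste0("K", 1:8), sample(0:3, 1))))
  pick <- sample(ids, 9)
  expect_equal(map_to_kos(pick, komap_r)$kos,
               sort(unique(unlist(komap_r$ko[komap_r$reaction_id %in% pick]))))
})

test_that("ko_map aggregates annotations across models", {
  cfg <- small_config(seed = 2, marker_presence_gap = 1)
  gg <- generate_toy_gems(cfg)
  km <- ko_map(gg$gems)
  marker <- gg$truth$marker_reactions
  got <- km$ko[match(marker, km$reaction_id)]
  expect_equal(sort(unique(unlist(got))),
               sort(unique(unname(cfg$marker_kos))))
})

test_that("presence-gap filter keeps reactions separating the model groups", {
  P <- rbind(e1 = c(rx = 1, ry = 1, rz = 0),
             e2 = c(rx = 1, ry = 0, rz = 0),
             c1 = c(rx = 0, ry = 1, rz = 0),
             c2 = c(rx = 0, ry = 0, rz = 0))
  groups <- tibble::tibble(
    model_id = c("e1", "e2", "c1", "c2"),
    group = c("disease-enriched", "disease-enriched",
              "control-enriched", "control-enriched"))
  kept <- presence_gap_filter(P, groups, min_gap = 0.2)
  expect_equal(kept, "rx")        # 100% vs 0%
  expect_false("ry" %in% kept)    # 50% vs 50%
  expect_false("rz" %in% kept)    # absent everywhere
  expect_error(presence_gap_filter(P, groups[1:2, ]), "group")

  # random instance vs explicit fraction computation
  set.seed(61)
  P2 <- matrix(rbinom(8 * 25, 1, 0.5), 8, 25,
               dimnames = list(sprintf("m%d", 1:8), sprintf("q%02d", 1:25)))
  g2 <- tibble::tibble(model_id = rownames(P2),
                       group = rep(c("disease-enriched", "control-enriched"), 4))
  kept2 <- presence_gap_filter(P2, g2, min_gap = 0.2)
  fr <- function(rows, j) mean(P2[rows, j])
  e_rows <- g2$model_id[g2$group == "disease-enriched"]
  c_rows <- g2$model_id[g2$group == "control-enriched"]
  manual <- colnames(P2)[vapply(colnames(P2), function(j)
    abs(fr(e_rows, j) - fr(c_rows, j)) > 0.2, TRUE)]
  expect_equal(kept2, sort(manual))
})
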