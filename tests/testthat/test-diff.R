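test_that("wilcoxon p matches the textbook separated case and symmetric null", {
  expect_equal(wilcoxon_two_sided(c(1.2, 3.4, 5.6), c(7.8, 9.1, 10.2)), 0.1)
  expect_equal(wilcoxon_two_sided(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(wilcoxon_two_sided(c(5, 5, 5), c(5, 5)), 1) # zero spread
  expect_error(wilcoxon_two_sided(numeric(), c(1)), "nonempty")
})

test_that("exact wilcoxon agrees with full enumeration for pooled n <= 12", {
  set.seed(13)
  for (k in 1:30) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    repeat { # draw until tie-free
      x <- round(rnorm(n1), 4); y <- round(rnorm(n2), 4)
      if (!anyDuplicated(c(x, y))) break
    }
    expect_equal(wilcoxon_two_sided(x, y), wilcoxon_enum_oracle(x, y),
                 tolerance = 1e-12, info = paste("case", k))
  }
})

test_that("wilcoxon p is invariant under strictly monotone transforms", {
  set.seed(3)
  x <- rexp(15); y <- rexp(18) * 1.5
  p0 <- wilcoxon_two_sided(x, y)
  expect_equal(wilcoxon_two_sided(log(x), log(y)), p0)
  expect_equal(wilcoxon_two_sided(x^3, y^3), p0)
  expect_equal(wilcoxon_two_sided(-1 / x, -1 / y), p0)
})

test_that("benjamini-hochberg matches the hand step-up and its invariants", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(benjamini_hochberg(c(1, 1)), c(1, 1))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "0, 1")

  set.seed(21)
  p <- runif(50)
  adj <- benjamini_hochberg(p)
  expect_equal(adj, bh_hand_oracle(p))
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  # permutation invariance
  perm <- sample(50)
  expect_equal(benjamini_hochberg(p[perm]), adj[perm])
})

test_that("the two-step rule selects only zero-vs-positive median features", {
  set.seed(8)
  n <- 20
  mk <- function(case, control) c(case, control)
  tbl <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:(2 * n)),
    # planted: zero in controls, positive in cases
    planted = mk(rexp(n) + 1, rep(0, n)),
    # significant shift but both medians positive
    shifted = mk(rexp(n) + 5, rexp(n) + 0.5),
    # nothing going on
    flat = rexp(2 * n))
  meta <- tibble::tibble(sample_id = tbl$sample_id,
                         group = rep(c("case", "control"), each = n))
  res <- differential_abundance(tbl, meta)
  sel <- select_significant_msps(tbl, meta, fdr_threshold = 0.01)
  expect_equal(sel$feature_id, "planted")
  expect_true(res$fdr[res$feature_id == "shifted"] < 0.01) # significant...
  expect_false("shifted" %in% sel$feature_id)              # ...but not selected
  expect_true(all(sel$fdr < 0.01))
  expect_error(differential_abundance(tbl[c(1, n + 1), ], meta), "at least 2")
})

test_that("enrichment direction follows the mean comparison with tie to control", {
  expect_equal(enrichment_direction(0.4, 0.1), "disease-enriched")
  expect_equal(enrichment_direction(0.1, 0.1), "control-enriched")
  # zero case mean with pseudo-count gives a negative fold change
  tbl <- tibble::tibble(
    sample_id = sprintf("s%d", 1:8),
    f = c(0, 0, 0, 0, 0.2, 0.25, 0.2, 0.22))
  meta <- tibble::tibble(sample_id = tbl$sample_id,
                         group = rep(c("case", "control"), each = 4))
  res <- differential_abundance(tbl, meta)
  expect_lt(res$fold_change, 0)
  expect_equal(res$direction, "control-enriched")
})

test_that("phylum aggregation is additive and matches a groupby oracle", {
  tbl <- tibble::tibble(sample_id = c("s1", "s2"),
                        m1 = c(0.1, 0.3), m2 = c(0.2, 0.1), m3 = c(0.7, 0.6))
  tax <- c(m1 = "Firmicutes", m2 = "Firmicutes", m3 = "Bacteroidetes")
  agg <- aggregate_by_phylum(tbl, tax)
  expect_equal(agg$Firmicutes, c(0.3, 0.4))
  expect_equal(agg$Bacteroidetes, c(0.7, 0.6))

  set.seed(30)
  m <- matrix(runif(10 * 50), 10, 50,
              dimnames = list(sprintf("s%d", 1:10), sprintf("f%02d", 1:50)))
  phyla <- sample(paste0("P", 1:5), 50, replace = TRUE)
  names(phyla) <- colnames(m)
  agg2 <- table_to_matrix(aggregate_by_phylum(m, phyla))
  for (p in unique(phyla))
    expect_equal(unname(agg2[, p]),
                 unname(rowSums(m[, phyla == p, drop = FALSE])))
})

test_that("unique union reproduces the study's selection arithmetic", {
  # per-disease selections sized 17 (obesity), 6 (T2D) and 25 (ACVD) where
  # the six T2D species are exactly the ones shared with ACVD
  obesity <- sprintf("ob_%02d", 1:17)
  shared <- sprintf("sh_%02d", 1:6)
  t2d <- shared
  acvd <- c(shared, sprintf("ac_%02d", 1:19))
  expect_length(t2d, 6); expect_length(acvd, 25)
  expect_length(unique_union(list(obesity, t2d, acvd)), 42)

  expect_length(unique_union(list("a", "b", "c")), 3)
  expect_equal(unique_union(list(c("x", "y"), c("x", "y"))), c("x", "y"))
})

test_that("on null data the selection rate respects the FDR target", {
  set.seed(77)
  n <- 30; nf <- 300
  m <- matrix(rexp(2 * n * nf), 2 * n, nf,
              dimnames = list(sprintf("s%02d", 1:(2 * n)),
                              sprintf("f%03d", 1:nf)))
  meta <- tibble::tibble(sample_id = rownames(m),
                         group = rep(c("case", "control"), each = n))
  res <- differential_abundance(m, meta)
  expect_lte(mean(res$fdr < 0.01), 0.01 + 0.02) # Monte-Carlo slack
})
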