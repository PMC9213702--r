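# Independent oracles used to validate the package's implementations.
# These deliberately use brute force (enumeration, explicit loops) and stay
# independent of the code paths they check.

# Enumerate all basic solutions of {A x = b, lb <= x <= ub} and return the
# best objective value: every vertex fixes n - rank(A) variables at a bound.
lp_vertex_oracle <- function(obj, A, b = NULL, lb, ub) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  if (is.null(b)) b <- numeric(m)
  best <- -Inf
  feasible <- FALSE
  basis_sets <- utils::combn(n, min(m, n), simplify = FALSE)
  for (bs in basis_sets) {
    nb <- setdiff(seq_len(n), bs)
    B <- A[, bs, drop = FALSE]
    if (abs(det(B)) < 1e-10) next
    # nonbasic vars at each combination of their bounds
    combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(nb)))
    if (length(nb) == 0L) combos <- data.frame(row.names = 1)
    for (k in seq_len(nrow(combos))) {
      x <- numeric(n)
      if (length(nb))
        x[nb] <- ifelse(unlist(combos[k, ]), ub[nb], lb[nb])
      rhs <- b - if (length(nb)) A[, nb, drop = FALSE] %*% x[nb] else 0
      xb <- tryCatch(solve(B, rhs), error = function(e) NULL)
      if (is.null(xb)) next
      x[bs] <- xb
      if (all(x >= lb - 1e-8) && all(x <= ub + 1e-8)) {
        feasible <- TRUE
        val <- sum(obj * x)
        if (val > best) best <- val
      }
    }
  }
  list(feasible = feasible, objective = best)
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of group
# labelings of the pooled sample (no-ties case).
wilcoxon_enum_oracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); m <- length(x)
  ranks <- rank(pooled)
  obs <- sum(ranks[seq_len(m)])
  all_w <- apply(utils::combn(n, m), 2, function(idx) sum(ranks[idx]))
  lo <- mean(all_w <= obs)
  hi <- mean(all_w >= obs)
  min(1, 2 * min(lo, hi))
}

# Hand-rolled Benjamini-Hochberg step-up.
bh_hand_oracle <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- numeric(m)
  running <- 1
  for (i in seq_along(o)) {
    k <- m - i + 1 # rank of this p in ascending order
    running <- min(running, p[o[i]] * m / k)
    adj[o[i]] <- running
  }
  adj
}

# Explicit triple-loop reaction abundance: sum over species of
# presence * abundance.
reaction_abundance_loop_oracle <- function(presence, abundance_matrix) {
  samples <- rownames(abundance_matrix)
  rxns <- colnames(presence)
  out <- matrix(0, length(samples), length(rxns),
                dimnames = list(samples, rxns))
  for (s in samples)
    for (j in rxns)
      for (sp in rownames(presence))
        if (sp %in% colnames(abundance_matrix))
          out[s, j] <- out[s, j] + presence[sp, j] * abundance_matrix[s, sp]
  out
}
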