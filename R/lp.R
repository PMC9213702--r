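#' Solve a bounded-variable linear program
#'
#' Solves `max (or min) c'x` subject to `A x = b` and `lb <= x <= ub` with a
#' two-phase primal simplex on the bounded-variable form. This is the flux
#' balance analysis work-horse: for FBA, `A` is the stoichiometric matrix,
#' `b = 0`, and the bounds are the reaction bounds.
#'
#' The implementation is a dense tableau simplex with Dantzig pricing and a
#' Bland anti-cycling fallback. All bounds must be finite (flux bounds are
#' conventionally capped at +/- 1000 mmol/gDW/h); phase-1 artificial
#' variables establish feasibility, phase 2 optimizes the objective.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A constraint matrix (m x n), dense or sparse ("Matrix").
#' @param b right-hand side (length m, default all zero).
#' @param lb,ub finite lower/upper variable bounds (length n).
#' @param maximize logical; maximize (default) or minimize.
#' @param tol pivot/feasibility tolerance.
#' @param max_iter iteration cap (default scales with problem size).
#'
#' @return A list with `status` ("optimal", "infeasible" or "unbounded"),
#'   `objective` (the optimal value, `NA` unless optimal) and `x` (a solution
#'   vector attaining it).
#' @export
solve_lp <- function(obj, A, b = NULL, lb, ub, maximize = TRUE,
                     tol = 1e-9, max_iter = NULL) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(obj) == n, length(lb) == n, length(ub) == n)
  if (is.null(b)) b <- numeric(m)
  stopifnot(length(b) == m)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("solve_lp() requires finite variable bounds")
  if (any(lb > ub + tol))
    stop("lower bound exceeds upper bound for some variable")
  cost <- if (maximize) as.numeric(obj) else -as.numeric(obj)

  # shift to y = x - lb in [0, w]
  w <- ub - lb
  b0 <- b - drop(A %*% lb)

  # artificial columns: identity signed to make initial basic values >= 0
  sgn <- ifelse(b0 >= 0, 1, -1)
  ntot <- n + m
  # tableau starts as B^{-1}[A | E] with B = E = diag(sgn)
  Tb <- cbind(A * sgn, diag(1, nrow = m, ncol = m))
  wa <- c(w, rep(Inf, m))
  basis <- n + seq_len(m)
  beta <- abs(b0)
  at_upper <- rep(FALSE, ntot) # state of nonbasic variables
  is_basic <- rep(FALSE, ntot)
  is_basic[basis] <- TRUE

  if (is.null(max_iter)) max_iter <- 200L * (m + n) + 1000L
  bland_after <- 40L * (m + n) + 200L

  run_phase <- function(cost_full, forbid) {
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter)
        stop("simplex iteration limit reached (", max_iter, ")")
      cB <- cost_full[basis]
      d <- cost_full - drop(cB %*% Tb)
      d[basis] <- 0
      improv <- (!is_basic) & !forbid & wa > tol &
        ((!at_upper & d > tol) | (at_upper & d < -tol))
      if (!any(improv)) return(invisible(NULL)) # optimal for this phase
      cand <- which(improv)
      j <- if (iter > bland_after) cand[1L] else cand[which.max(abs(d[cand]))]
      s <- if (at_upper[j]) -1 else 1
      g <- s * Tb[, j]
      # ratio test
      t_flip <- wa[j]
      t_best <- t_flip
      r <- 0L
      dec <- which(g > tol)
      if (length(dec)) {
        td <- beta[dec] / g[dec]
        kd <- which.min(td)
        if (td[kd] < t_best - 0) { t_best <- td[kd]; r <- dec[kd] }
      }
      inc <- which(g < -tol & is.finite(wa[basis]))
      if (length(inc)) {
        ti <- (wa[basis[inc]] - beta[inc]) / (-g[inc])
        ki <- which.min(ti)
        if (ti[ki] < t_best) { t_best <- ti[ki]; r <- inc[ki] }
      }
      if (!is.finite(t_best)) return("unbounded")
      t_best <- max(t_best, 0)
      beta <<- beta - t_best * g
      if (r == 0L) { # bound flip, basis unchanged
        at_upper[j] <<- !at_upper[j]
        next
      }
      leave <- basis[r]
      at_upper[leave] <<- g[r] < 0 # hit its upper bound if it was increasing
      is_basic[leave] <<- FALSE
      enter_val <- (if (at_upper[j]) wa[j] else 0) + s * t_best
      basis[r] <<- j
      is_basic[j] <<- TRUE
      at_upper[j] <<- FALSE
      piv <- Tb[r, j]
      Tb[r, ] <<- Tb[r, ] / piv
      other <- which(abs(Tb[, j]) > 0 & seq_len(m) != r)
      if (length(other))
        Tb[other, ] <<- Tb[other, ] - outer(Tb[other, j], Tb[r, ])
      beta[r] <<- enter_val
      beta[beta < 0 & beta > -1e-7] <<- 0
    }
  }

  # phase 1: drive artificials to zero
  c1 <- c(rep(0, n), rep(-1, m))
  st <- run_phase(c1, forbid = rep(FALSE, ntot))
  art_basic <- basis > n
  infeas <- sum(beta[art_basic])
  if (!is.null(st) || infeas > 1e-7)
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  beta[art_basic & beta < tol] <- 0
  wa[n + seq_len(m)] <- 0 # artificials frozen at zero for phase 2

  c2 <- c(cost, rep(0, m))
  st <- run_phase(c2, forbid = c(rep(FALSE, n), rep(TRUE, m)))
  if (!is.null(st))
    return(list(status = "unbounded", objective = NA_real_, x = NULL))

  y <- ifelse(at_upper[seq_len(n)], w, 0)
  y[basis[basis <= n]] <- beta[basis <= n]
  x <- y + lb
  x <- pmin(pmax(x, lb), ub)
  list(status = "optimal",
       objective = sum(as.numeric(obj) * x),
       x = x)
}
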