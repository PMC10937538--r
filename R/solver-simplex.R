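# Dense-tableau simplex solvers.
#
# Both methods run on canonical shapes produced by lp-standardize.R. The
# primal solver is a two-phase method with artificial variables; the dual
# solver starts from the all-slack basis of the inequality form, which is
# dual-feasible whenever all costs are nonnegative (the montage LPs always
# are) and otherwise gains dual feasibility through one pivot on a big-M
# aggregate bound row. Dantzig pricing with a Bland fallback guards against
# cycling on degenerate vertices.

simplex_pivot <- function(Tab, zrow, basis, i, j) {
  piv <- Tab[i, j]
  Tab[i, ] <- Tab[i, ] / piv
  others <- setdiff(seq_len(nrow(Tab)), i)
  if (length(others) > 0L) {
    Tab[others, ] <- Tab[others, ] - outer(Tab[others, j], Tab[i, ])
  }
  zrow <- zrow - zrow[j] * Tab[i, ]
  basis[i] <- j
  list(Tab = Tab, zrow = zrow, basis = basis)
}

# Minimize cost'x over {A x = b, x >= 0} given a starting basic feasible
# basis whose columns form unit vectors in Tab. `allowed` masks columns that
# may enter (used to lock artificials out in phase 2).
simplex_iterate <- function(Tab, basis, cost, allowed, tol = 1e-9,
                            max_iter = 10000L, iter_used = 0L) {
  m <- nrow(Tab); ncols <- ncol(Tab) - 1L
  bcol <- ncols + 1L
  zrow <- c(cost, 0) - as.numeric(cost[basis] %*% Tab)
  it <- iter_used
  stall <- 0L
  last_obj <- Inf
  repeat {
    cand <- which(allowed & zrow[seq_len(ncols)] < -tol)
    if (length(cand) == 0L) {
      return(list(status = "optimal", Tab = Tab, basis = basis,
                  iterations = it))
    }
    if (it - iter_used >= max_iter) {
      return(list(status = "iteration_limit", Tab = Tab, basis = basis,
                  iterations = it))
    }
    bland <- stall > 2L * (m + ncols)
    j <- if (bland) cand[1L] else cand[which.min(zrow[cand])]
    col <- Tab[, j]
    pos <- which(col > tol)
    if (length(pos) == 0L) {
      return(list(status = "unbounded", Tab = Tab, basis = basis,
                  iterations = it))
    }
    ratios <- Tab[pos, bcol] / col[pos]
    rmin <- min(ratios)
    ties <- pos[ratios <= rmin + tol]
    i <- ties[which.min(basis[ties])]
    res <- simplex_pivot(Tab, zrow, basis, i, j)
    Tab <- res$Tab; zrow <- res$zrow; basis <- res$basis
    it <- it + 1L
    obj <- -zrow[bcol]
    if (obj < last_obj - tol) {
      last_obj <- obj; stall <- 0L
    } else {
      stall <- stall + 1L
    }
  }
}

solve_primal_simplex_standard <- function(A, b, c, tol = 1e-9,
                                          max_iter = 20000L) {
  m <- nrow(A); n <- ncol(A)
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]

  Tab <- cbind(A, diag(1, m), b)
  basis <- n + seq_len(m)
  scale_b <- max(1, max(abs(b)))

  # phase 1: drive the artificial variables to zero
  cost1 <- c(rep(0, n), rep(1, m))
  ph1 <- simplex_iterate(Tab, basis, cost1, allowed = rep(TRUE, n + m),
                         tol = tol, max_iter = max_iter)
  if (ph1$status == "iteration_limit") {
    return(list(status = "iteration_limit", x = NULL,
                iterations = ph1$iterations))
  }
  Tab <- ph1$Tab; basis <- ph1$basis
  bcol <- n + m + 1L
  phase1_obj <- sum(Tab[basis > n, bcol])
  if (phase1_obj > 1e-7 * scale_b) {
    return(list(status = "infeasible", x = NULL, iterations = ph1$iterations))
  }
  # pivot residual zero-level artificials out where possible
  for (i in which(basis > n)) {
    j <- which(abs(Tab[i, seq_len(n)]) > 1e-7)
    if (length(j) > 0L) {
      res <- simplex_pivot(Tab, numeric(bcol), basis, i, j[1L])
      Tab <- res$Tab; basis <- res$basis
    }
  }

  cost2 <- c(c, rep(0, m))
  allowed <- c(rep(TRUE, n), rep(FALSE, m))
  ph2 <- simplex_iterate(Tab, basis, cost2, allowed, tol = tol,
                         max_iter = max_iter, iter_used = ph1$iterations)
  if (ph2$status %in% c("iteration_limit", "unbounded")) {
    return(list(status = ph2$status, x = NULL, iterations = ph2$iterations))
  }
  x <- numeric(n)
  real <- ph2$basis <= n
  x[ph2$basis[real]] <- ph2$Tab[real, bcol]
  list(status = "optimal", x = x, iterations = ph2$iterations)
}

solve_dual_simplex_inequality <- function(A, b, c, tol = 1e-9,
                                          max_iter = 20000L) {
  m <- nrow(A); n <- ncol(A)
  neg_cost <- which(c < -tol)
  bigM_used <- length(neg_cost) > 0L
  if (bigM_used) {
    # aggregate bound row grants a dual-feasible start for negative costs
    bigM <- 1e8 * max(1, max(abs(b)), max(abs(c)))
    A <- rbind(A, as.numeric(seq_len(n) %in% neg_cost))
    b <- c(b, bigM)
    m <- m + 1L
  }
  Tab <- cbind(A, diag(1, m), b)
  basis <- n + seq_len(m)
  ncols <- n + m
  bcol <- ncols + 1L
  zrow <- c(c, rep(0, m), 0)
  if (bigM_used) {
    q <- neg_cost[which.min(c[neg_cost])]
    res <- simplex_pivot(Tab, zrow, basis, m, q)
    Tab <- res$Tab; zrow <- res$zrow; basis <- res$basis
  }

  it <- 0L; stall <- 0L; last_inf <- Inf
  repeat {
    bvals <- Tab[, bcol]
    viol <- which(bvals < -tol)
    if (length(viol) == 0L) break
    if (it >= max_iter) {
      return(list(status = "iteration_limit", x = NULL, iterations = it))
    }
    bland <- stall > 2L * (m + ncols)
    i <- if (bland) viol[1L] else viol[which.min(bvals[viol])]
    row <- Tab[i, seq_len(ncols)]
    elig <- which(row < -tol)
    if (length(elig) == 0L) {
      return(list(status = "infeasible", x = NULL, iterations = it))
    }
    ratios <- zrow[elig] / (-row[elig])
    rmin <- min(ratios)
    ties <- elig[ratios <= rmin + tol]
    j <- ties[1L]
    res <- simplex_pivot(Tab, zrow, basis, i, j)
    Tab <- res$Tab; zrow <- res$zrow; basis <- res$basis
    it <- it + 1L
    inf_now <- -sum(pmin(Tab[, bcol], 0))
    if (inf_now < last_inf - tol) {
      last_inf <- inf_now; stall <- 0L
    } else {
      stall <- stall + 1L
    }
  }
  x <- numeric(ncols)
  x[basis] <- Tab[, bcol]
  if (bigM_used && sum(x[neg_cost]) > 0.99 * b[m]) {
    return(list(status = "unbounded", x = NULL, iterations = it))
  }
  list(status = "optimal", x = x[seq_len(n)], iterations = it)
}

solver_primal_simplex <- function(lp, tol = 1e-9, max_iter = 20000L) {
  if (lp_check_bounds(lp)) {
    return(list(status = "infeasible", z = NULL, objective = NA_real_,
                iterations = 0L))
  }
  sf <- lp_to_equality_form(lp)
  res <- solve_primal_simplex_standard(sf$A, sf$b, sf$c, tol = tol,
                                       max_iter = max_iter)
  if (res$status != "optimal") {
    return(list(status = res$status, z = NULL, objective = NA_real_,
                iterations = res$iterations))
  }
  z <- res$x[seq_len(sf$n_orig)] + sf$shift
  list(status = "optimal", z = z, objective = sum(lp$c * z),
       iterations = res$iterations)
}

solver_dual_simplex <- function(lp, tol = 1e-9, max_iter = 20000L) {
  if (lp_check_bounds(lp)) {
    return(list(status = "infeasible", z = NULL, objective = NA_real_,
                iterations = 0L))
  }
  sf <- lp_to_inequality_form(lp)
  res <- solve_dual_simplex_inequality(sf$A, sf$b, sf$c, tol = tol,
                                       max_iter = max_iter)
  if (res$status != "optimal") {
    return(list(status = res$status, z = NULL, objective = NA_real_,
                iterations = res$iterations))
  }
  z <- res$x[seq_len(sf$n_orig)] + sf$shift
  list(status = "optimal", z = z, objective = sum(lp$c * z),
       iterations = res$iterations)
}
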