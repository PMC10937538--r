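# Conversions from the bounded general form
#   min c'z  s.t.  A_ub z <= b_ub,  A_eq z = b_eq,  lb <= z <= ub
# (all lower bounds finite; upper bounds may be +Inf) to the two canonical
# shapes the internal solvers consume. Variables are shifted by lb so the
# canonical variable is x = z - lb >= 0; the objective constant c'lb is
# carried along and restored in reports.

lp_check_bounds <- function(lp) {
  if (any(!is.finite(lp$lb))) {
    abort("internal solvers require finite lower bounds on all variables.")
  }
  # contradictory bounds make the whole program infeasible before any solve
  any(lp$lb > lp$ub + 1e-12)
}

# Equality standard form: min c'x, A x = b, x >= 0 (slack columns appended
# for inequality and finite-upper-bound rows).
lp_to_equality_form <- function(lp) {
  n <- length(lp$c)
  fin_ub <- which(is.finite(lp$ub))
  m_ub <- nrow(lp$A_ub); m_eq <- nrow(lp$A_eq); m_bd <- length(fin_ub)
  m <- m_ub + m_eq + m_bd
  n_tot <- n + m_ub + m_bd

  A <- matrix(0, m, n_tot)
  b <- numeric(m)
  if (m_ub > 0L) {
    A[seq_len(m_ub), seq_len(n)] <- lp$A_ub
    A[cbind(seq_len(m_ub), n + seq_len(m_ub))] <- 1
    b[seq_len(m_ub)] <- lp$b_ub - as.numeric(lp$A_ub %*% lp$lb)
  }
  if (m_eq > 0L) {
    A[m_ub + seq_len(m_eq), seq_len(n)] <- lp$A_eq
    b[m_ub + seq_len(m_eq)] <- lp$b_eq - as.numeric(lp$A_eq %*% lp$lb)
  }
  if (m_bd > 0L) {
    A[cbind(m_ub + m_eq + seq_len(m_bd), fin_ub)] <- 1
    A[cbind(m_ub + m_eq + seq_len(m_bd), n + m_ub + seq_len(m_bd))] <- 1
    b[m_ub + m_eq + seq_len(m_bd)] <- lp$ub[fin_ub] - lp$lb[fin_ub]
  }
  cc <- c(lp$c, rep(0, m_ub + m_bd))
  list(A = A, b = b, c = cc, n_orig = n, shift = lp$lb,
       constant = sum(lp$c * lp$lb))
}

# Inequality canonical form: min c'x, A x <= b, x >= 0 (equalities written
# as opposing inequality pairs); used by the dual simplex, whose all-slack
# starting basis lives in this shape.
lp_to_inequality_form <- function(lp) {
  n <- length(lp$c)
  fin_ub <- which(is.finite(lp$ub))
  b_ub_sh <- lp$b_ub - as.numeric(lp$A_ub %*% lp$lb)
  b_eq_sh <- lp$b_eq - as.numeric(lp$A_eq %*% lp$lb)
  A <- rbind(lp$A_ub, lp$A_eq, -lp$A_eq,
             diag(1, n)[fin_ub, , drop = FALSE])
  b <- c(b_ub_sh, b_eq_sh, -b_eq_sh, lp$ub[fin_ub] - lp$lb[fin_ub])
  list(A = A, b = b, c = lp$c, n_orig = n, shift = lp$lb,
       constant = sum(lp$c * lp$lb))
}

#' Check a candidate solution against an LP's constraints
#'
#' Independent feasibility check: maximum violation of the inequality,
#' equality, and bound constraints of an `lp_data`, in the problem's own
#' units.
#'
#' @param lp An `lp_data`.
#' @param z Candidate solution in the original variables.
#' @return A list with per-constraint-class maximum violations and the
#'   overall `max_violation`.
#' @export
check_lp_solution <- function(lp, z) {
  z <- as.numeric(z)
  stopifnot(length(z) == length(lp$c))
  v_ub <- if (nrow(lp$A_ub) > 0L) max(c(0, lp$A_ub %*% z - lp$b_ub)) else 0
  v_eq <- if (nrow(lp$A_eq) > 0L) max(c(0, abs(lp$A_eq %*% z - lp$b_eq))) else 0
  v_lb <- max(c(0, lp$lb - z))
  v_ub_bound <- max(c(0, z - lp$ub), na.rm = TRUE)
  list(inequality = v_ub, equality = v_eq, lower = v_lb, upper = v_ub_bound,
       max_violation = max(v_ub, v_eq, v_lb, v_ub_bound))
}
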