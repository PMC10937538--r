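# Epigraph assembly of the L1-fitted, L1-penalized montage problem.
#
# The montage y (mA) minimizes
#   || L1 y - x1 ||_1  +  sum_m max{ |nu^-1 (L2 y)_m| , eps }  +  alpha zeta ||y||_1
# subject to |y_l| <= gamma, ||y||_1 <= mu, sum(y) = 0.
# Majorants t (fit residuals), r (nuisance, floored at eps) and u (|y|)
# linearize every absolute value; the eps floor makes sum(r) carry the
# constant M*eps region exactly as the objective is written, which leaves
# the argmin unchanged but keeps reported objective values comparable
# across (alpha, eps).

#' Configuration of the montage optimization problem
#'
#' @param alpha L1-regularization weight (linear scale, dimensionless,
#'   `>= 0`).
#' @param epsilon Nuisance threshold in `[0, 1]` (relative to the scaling
#'   `nu = ||x||_inf`).
#' @param gamma Per-channel current cap in mA (default 2.0).
#' @param mu Total current dose cap in mA (default 4.0).
#' @return An `l1l1_config` object.
#' @examples
#' l1l1_config(alpha = 1e-3, epsilon = 0.1)
#' @export
l1l1_config <- function(alpha, epsilon, gamma = 2.0, mu = 4.0) {
  check_scalar(alpha, "alpha", 0, Inf)
  check_scalar(epsilon, "epsilon", 0, 1)
  check_scalar(gamma, "gamma", 0, Inf, allow_equal = FALSE)
  check_scalar(mu, "mu", 0, Inf, allow_equal = FALSE)
  structure(list(alpha = alpha, epsilon = epsilon, gamma = gamma, mu = mu),
            class = "l1l1_config")
}

new_lp_data <- function(c_obj, A_ub, b_ub, A_eq, b_eq, lb, ub, layout,
                        constant = 0) {
  n <- length(c_obj)
  stopifnot(ncol(A_ub) == n, ncol(A_eq) == n, length(lb) == n,
            length(ub) == n, nrow(A_ub) == length(b_ub),
            nrow(A_eq) == length(b_eq))
  structure(list(c = c_obj, A_ub = A_ub, b_ub = b_ub, A_eq = A_eq,
                 b_eq = b_eq, lb = lb, ub = ub, layout = layout,
                 constant = constant),
            class = "lp_data")
}

#' @export
print.lp_data <- function(x, ...) {
  cat(sprintf("<lp_data> %d variables, %d inequality rows, %d equality row(s)\n",
              length(x$c), nrow(x$A_ub), nrow(x$A_eq)))
  if (!is.null(x$layout)) {
    cat("  layout:", paste(names(x$layout), unlist(x$layout), sep = "=",
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' Assemble the montage linear program
#'
#' Encodes the L1-fitted, L1-penalized problem as a standard-form LP over
#' the variable vector `[y (L, bounds +/- gamma), u (L, |y| majorants),
#' t (T, fit-residual majorants), r (M, nuisance majorants with lower bound
#' epsilon)]`:
#' minimize `sum(t) + sum(r) + alpha * zeta * sum(u)` subject to
#' `-t <= L1 y - x1 <= t`, `-r <= nu^-1 L2 y <= r` (with `r >= epsilon`),
#' `-u <= y <= u`, `sum(u) <= mu`, `sum(y) = 0`, `|y| <= gamma`.
#'
#' @param system A `focused_system`.
#' @param config An `l1l1_config`.
#' @return An `lp_data` object with a documented `layout` describing the
#'   variable blocks.
#' @examples
#' lf <- generate_sphere_leadfield(4, 3, seed = 1)
#' sys <- build_focused_system(lf, target_spec(1, c(0, 0, 1)))
#' lp <- build_l1l1_lp(sys, l1l1_config(1e-3, 0.1))
#' length(lp$c)  # 2*4 + 1 + 8
#' @export
build_l1l1_lp <- function(system, config) {
  stopifnot(inherits(system, "focused_system"), inherits(config, "l1l1_config"))
  L1 <- system$L1; L2 <- system$L2; x1 <- system$x1
  L <- ncol(L1); Tn <- nrow(L1); M <- nrow(L2)
  if (Tn == 0L) abort("empty focused block L1.")
  if (system$nu <= 0) abort("degenerate target: nu = ||x||_inf is zero.")
  n <- 2L * L + Tn + M
  iy <- seq_len(L); iu <- L + seq_len(L)
  it <- 2L * L + seq_len(Tn); ir <- 2L * L + Tn + seq_len(M)

  c_obj <- numeric(n)
  c_obj[it] <- 1
  c_obj[ir] <- 1
  c_obj[iu] <- config$alpha * system$zeta

  n_ub <- 2L * Tn + 2L * M + 2L * L + 1L
  A_ub <- matrix(0, n_ub, n)
  b_ub <- numeric(n_ub)
  row <- 0L
  # fit residual majorants:  L1 y - t <= x1 ; -L1 y - t <= -x1
  A_ub[row + seq_len(Tn), iy] <- L1
  A_ub[cbind(row + seq_len(Tn), it)] <- -1
  b_ub[row + seq_len(Tn)] <- x1
  row <- row + Tn
  A_ub[row + seq_len(Tn), iy] <- -L1
  A_ub[cbind(row + seq_len(Tn), it)] <- -1
  b_ub[row + seq_len(Tn)] <- -x1
  row <- row + Tn
  # nuisance majorants: +/- nu^-1 L2 y - r <= 0
  if (M > 0L) {
    A_ub[row + seq_len(M), iy] <- L2 / system$nu
    A_ub[cbind(row + seq_len(M), ir)] <- -1
    row <- row + M
    A_ub[row + seq_len(M), iy] <- -L2 / system$nu
    A_ub[cbind(row + seq_len(M), ir)] <- -1
    row <- row + M
  }
  # absolute-value majorants: +/- y - u <= 0
  A_ub[cbind(row + seq_len(L), iy)] <- 1
  A_ub[cbind(row + seq_len(L), iu)] <- -1
  row <- row + L
  A_ub[cbind(row + seq_len(L), iy)] <- -1
  A_ub[cbind(row + seq_len(L), iu)] <- -1
  row <- row + L
  # dose: sum(u) <= mu
  A_ub[row + 1L, iu] <- 1
  b_ub[row + 1L] <- config$mu

  A_eq <- matrix(0, 1L, n)
  A_eq[1L, iy] <- 1
  b_eq <- 0

  lb <- c(rep(-config$gamma, L), rep(0, L), rep(0, Tn),
          rep(config$epsilon, M))
  ub <- c(rep(config$gamma, L), rep(config$gamma, L), rep(Inf, Tn),
          rep(Inf, M))

  new_lp_data(c_obj, A_ub, b_ub, A_eq, b_eq, lb, ub,
              layout = list(L = L, T = Tn, M = M,
                            y = iy, u = iu, t = it, r = ir))
}

#' Evaluate the montage objective directly
#'
#' Computes `sum|L1 y - x1| + sum_m max{|nu^-1 (L2 y)_m|, epsilon} +
#' alpha * zeta * ||y||_1` for a given current pattern, independently of the
#' LP encoding, so solver outputs can be verified against the definition.
#'
#' @param system A `focused_system`.
#' @param config An `l1l1_config`.
#' @param y Numeric current pattern of length L (mA).
#' @return The objective value (a number).
#' @export
objective_value <- function(system, config, y) {
  stopifnot(inherits(system, "focused_system"), inherits(config, "l1l1_config"))
  y <- as.numeric(y)
  if (length(y) != ncol(system$L1)) abort("`y` has the wrong length.")
  fit <- sum(abs(system$L1 %*% y - system$x1))
  nuis <- if (nrow(system$L2) > 0L) {
    sum(pmax(abs(system$L2 %*% y) / system$nu, config$epsilon))
  } else 0
  fit + nuis + config$alpha * system$zeta * sum(abs(y))
}

#' Constraint support of a current pattern
#'
#' The nuisance indices whose response magnitude meets the threshold,
#' `{m : |(L2 y)_m| >= epsilon * nu}` — the entries that actively
#' contribute to the objective rather than resting on the threshold floor.
#'
#' @inheritParams objective_value
#' @return An integer vector of 1-based nuisance row indices.
#' @export
constraint_support <- function(system, config, y) {
  stopifnot(inherits(system, "focused_system"), inherits(config, "l1l1_config"))
  y <- as.numeric(y)
  if (length(y) != ncol(system$L1)) abort("`y` has the wrong length.")
  if (nrow(system$L2) == 0L) return(integer())
  which(abs(as.numeric(system$L2 %*% y)) >= config$epsilon * system$nu)
}

#' Serialize an LP to a debug JSON file
#'
#' Writes the dense constraint data to JSON for solver-independent
#' inspection.
#'
#' @param lp An `lp_data`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
lp_to_json <- function(lp, path) {
  stopifnot(inherits(lp, "lp_data"))
  jsonlite::write_json(
    list(c = lp$c, A_ub = apply(lp$A_ub, 1, identity, simplify = FALSE),
         b_ub = lp$b_ub,
         A_eq = apply(lp$A_eq, 1, identity, simplify = FALSE),
         b_eq = lp$b_eq, lb = lp$lb, ub = lp$ub,
         layout = lp$layout[c("L", "T", "M")]),
    path, digits = NA)
  invisible(path)
}
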