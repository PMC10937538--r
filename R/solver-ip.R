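# Mehrotra predictor-corrector primal-dual interior-point method on the
# equality standard form  min c'x, A x = b, x >= 0.
#
# Normal-equations variant: each Newton step solves (A D A') dlambda = rhs
# with D = diag(x / s) by Cholesky, with a diagonal jitter escalation when
# the factorization degenerates near the optimal face.

ip_factor_normal <- function(A, At, d) {
  M <- A %*% (d * At)
  jitter <- 0
  for (k in 0:6) {
    R <- tryCatch(chol(M + diag(jitter, nrow(M))), error = function(e) NULL)
    if (!is.null(R)) return(R)
    jitter <- if (jitter == 0) 1e-12 * max(diag(M)) else jitter * 100
  }
  abort("interior-point normal equations are numerically singular.")
}

ip_chol_solve <- function(R, rhs) {
  backsolve(R, backsolve(R, rhs, transpose = TRUE))
}

# Ruiz equilibration: symmetric inf-norm row/column scaling that evens out
# the wildly mixed magnitudes of the montage LPs (field rows ~0.1, bound
# rows 1, threshold floors down to 1e-8) before the Newton iterations.
ip_equilibrate <- function(A, b, c, passes = 3L) {
  m <- nrow(A); n <- ncol(A)
  dr <- rep(1, m); dc <- rep(1, n)
  for (k in seq_len(passes)) {
    rmax <- apply(abs(A), 1, max); rmax[rmax == 0] <- 1
    A <- A / sqrt(rmax)
    dr <- dr / sqrt(rmax)
    cmax <- apply(abs(A), 2, max); cmax[cmax == 0] <- 1
    A <- t(t(A) / sqrt(cmax))
    dc <- dc / sqrt(cmax)
  }
  list(A = A, b = dr * b, c = dc * c, dr = dr, dc = dc)
}

solve_ip_standard <- function(A, b, c, tol = 1e-8, max_iter = 100L) {
  m <- nrow(A); n <- ncol(A)
  At <- t(A)
  # least-squares starting point (Mehrotra's heuristic)
  AAt <- A %*% At
  AAt <- AAt + diag(1e-10 * max(1, sum(diag(AAt))) / m, m)
  R <- chol(AAt)
  x <- as.numeric(At %*% ip_chol_solve(R, b))
  lambda <- as.numeric(ip_chol_solve(R, A %*% c))
  s <- c - as.numeric(At %*% lambda)
  dx <- max(-1.5 * min(x), 0); ds <- max(-1.5 * min(s), 0)
  x <- x + dx; s <- s + ds
  xs <- sum(x * s)
  x <- x + 0.5 * xs / max(sum(s), 1e-12)
  s <- s + 0.5 * xs / max(sum(x), 1e-12)
  x <- pmax(x, 1e-10); s <- pmax(s, 1e-10)

  nb <- 1 + sqrt(sum(b^2)); nc <- 1 + sqrt(sum(c^2))
  # precision the endgame can genuinely reach before the scaling matrix
  # degenerates; iterates at this merit are accepted when tol is unreachable
  floor_tol <- max(1e-7, tol)
  best <- list(merit = Inf)
  stall <- 0L

  for (iter in seq_len(max_iter)) {
    rb <- as.numeric(A %*% x) - b
    rc <- as.numeric(At %*% lambda) + s - c
    mu <- sum(x * s) / n
    prim_res <- sqrt(sum(rb^2)) / nb
    dual_res <- sqrt(sum(rc^2)) / nc
    gap <- mu * n / (1 + abs(sum(c * x)))
    merit <- max(prim_res, dual_res, gap)

    if (merit < tol) {
      return(list(status = "optimal", x = x, lambda = lambda, s = s,
                  iterations = iter - 1L))
    }
    if (merit < best$merit) {
      if (merit < best$merit * 0.999) stall <- 0L
      best <- list(merit = merit, x = x, lambda = lambda, s = s,
                   prim = prim_res, iter = iter - 1L)
    } else {
      stall <- stall + 1L
    }
    diverged <- !all(is.finite(x)) || !all(is.finite(s)) ||
      max(x) > 1e14 || max(s) > 1e14
    if (diverged || stall > 12L || (mu < 1e-18 && merit > tol)) {
      if (best$merit < floor_tol) {
        return(list(status = "optimal", x = best$x, lambda = best$lambda,
                    s = best$s, iterations = best$iter))
      }
      status <- if (!diverged && best$merit > 1e-4 && best$prim > 1e-5) {
        "infeasible"
      } else {
        "numerical_failure"
      }
      return(list(status = status, x = x, lambda = lambda, s = s,
                  iterations = iter - 1L))
    }

    d <- pmin(pmax(x / s, 1e-16), 1e16)
    Rn <- ip_factor_normal(A, At, d)
    # affine-scaling predictor
    rhs_aff <- -rb - as.numeric(A %*% (d * rc - x))
    dl_aff <- ip_chol_solve(Rn, rhs_aff)
    ds_aff <- -rc - as.numeric(At %*% dl_aff)
    dx_aff <- -x - d * ds_aff

    ap_aff <- step_length(x, dx_aff)
    ad_aff <- step_length(s, ds_aff)
    mu_aff <- sum((x + ap_aff * dx_aff) * (s + ad_aff * ds_aff)) / n
    sigma <- (mu_aff / mu)^3

    # corrector with centering
    comp <- (dx_aff * ds_aff - sigma * mu) / s
    rhs_cc <- -rb - as.numeric(A %*% (d * rc - x - comp))
    dl <- ip_chol_solve(Rn, rhs_cc)
    ds_step <- -rc - as.numeric(At %*% dl)
    dx <- -x - comp - d * ds_step

    ap <- min(1, 0.9995 * step_length(x, dx))
    ad <- min(1, 0.9995 * step_length(s, ds_step))
    x <- x + ap * dx
    lambda <- lambda + ad * dl
    s <- s + ad * ds_step
  }
  if (best$merit < floor_tol) {
    return(list(status = "optimal", x = best$x, lambda = best$lambda,
                s = best$s, iterations = best$iter))
  }
  list(status = "iteration_limit", x = x, lambda = lambda, s = s,
       iterations = max_iter)
}

step_length <- function(v, dv) {
  neg <- dv < 0
  if (!any(neg)) return(1)
  min(1, min(-v[neg] / dv[neg]))
}

solver_interior_point <- function(lp, tol = 1e-8, max_iter = 100L) {
  if (lp_check_bounds(lp)) {
    return(list(status = "infeasible", z = NULL, objective = NA_real_,
                iterations = 0L))
  }
  sf <- lp_to_equality_form(lp)
  eq <- ip_equilibrate(sf$A, sf$b, sf$c)
  res <- solve_ip_standard(eq$A, eq$b, eq$c, tol = tol, max_iter = max_iter)
  if (res$status != "optimal") {
    return(list(status = res$status, z = NULL, objective = NA_real_,
                iterations = res$iterations))
  }
  x_orig <- eq$dc * res$x
  z <- x_orig[seq_len(sf$n_orig)] + sf$shift
  list(status = "optimal", z = z,
       objective = sum(lp$c * z), iterations = res$iterations)
}
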