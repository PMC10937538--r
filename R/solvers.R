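# Uniform solver interface: a registry maps algorithm classes
# (interior-point / primal-simplex / dual-simplex) to backends, every solve
# returns a status-tagged report, and compare_backends() sweeps instance
# families across backends for algorithm-class comparisons.

SOLVER_ALGORITHMS <- c("interior-point", "primal-simplex", "dual-simplex")

the_registry <- new.env(parent = emptyenv())

register_default_solvers <- function() {
  the_registry$backends <- list(
    `internal-ip` = list(algorithm = "interior-point",
                         fun = solver_interior_point),
    `internal-ps` = list(algorithm = "primal-simplex",
                         fun = solver_primal_simplex),
    `internal-ds` = list(algorithm = "dual-simplex",
                         fun = solver_dual_simplex)
  )
}

#' Solver backend registry
#'
#' `solver_registry()` lists the registered LP backends; `register_solver()`
#' adds one (a function taking `(lp, tol, max_iter)` and returning a list
#' with `status`, `z`, `objective`, `iterations`), keyed by the algorithm
#' class it implements.
#'
#' @param name Backend name.
#' @param algorithm One of `"interior-point"`, `"primal-simplex"`,
#'   `"dual-simplex"`.
#' @param fun Backend function.
#' @return `solver_registry()` returns a tibble of registered backends.
#' @export
solver_registry <- function() {
  if (is.null(the_registry$backends)) register_default_solvers()
  tibble(backend = names(the_registry$backends),
         algorithm = vapply(the_registry$backends, `[[`, "", "algorithm"))
}

#' @rdname solver_registry
#' @export
register_solver <- function(name, algorithm, fun) {
  algorithm <- match.arg(algorithm, SOLVER_ALGORITHMS)
  if (is.null(the_registry$backends)) register_default_solvers()
  the_registry$backends[[name]] <- list(algorithm = algorithm, fun = fun)
  invisible(name)
}

#' Describe which LP algorithm to run
#'
#' @param algorithm Algorithm class: `"interior-point"` (default),
#'   `"primal-simplex"`, or `"dual-simplex"`.
#' @param backend Optional backend name; by default the first registered
#'   backend implementing `algorithm` is used.
#' @param tol Feasibility/optimality tolerance (default 1e-8).
#' @param max_iter Iteration cap.
#' @return A `solver_spec` object.
#' @examples
#' solver_spec("dual-simplex")
#' @export
solver_spec <- function(algorithm = "interior-point", backend = NULL,
                        tol = 1e-8, max_iter = NULL) {
  algorithm <- match.arg(algorithm, SOLVER_ALGORITHMS)
  check_scalar(tol, "tol", 0, Inf, allow_equal = FALSE)
  if (is.null(max_iter)) {
    max_iter <- if (algorithm == "interior-point") 100L else 20000L
  }
  structure(list(algorithm = algorithm, backend = backend, tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "solver_spec")
}

resolve_backend <- function(spec) {
  if (is.null(the_registry$backends)) register_default_solvers()
  if (!is.null(spec$backend)) {
    entry <- the_registry$backends[[spec$backend]]
    if (is.null(entry)) {
      abort(sprintf("no registered solver backend named '%s'.", spec$backend))
    }
    if (entry$algorithm != spec$algorithm) {
      abort(sprintf("backend '%s' implements %s, not %s.",
                    spec$backend, entry$algorithm, spec$algorithm))
    }
    return(c(entry, list(name = spec$backend)))
  }
  for (nm in names(the_registry$backends)) {
    if (the_registry$backends[[nm]]$algorithm == spec$algorithm) {
      return(c(the_registry$backends[[nm]], list(name = nm)))
    }
  }
  abort(sprintf("no registered backend implements the %s algorithm.",
                spec$algorithm))
}

#' Solve a linear program
#'
#' Dispatches an `lp_data` to the backend selected by `spec` and returns a
#' uniform report. On `status = "optimal"` the solution is additionally
#' verified against the LP's own constraints; a violation beyond 10x the
#' solver tolerance downgrades the status to `"numerical_failure"`.
#'
#' @param lp An `lp_data`.
#' @param spec A `solver_spec` (default: interior point).
#' @return A `solve_report`: list with `status` (one of optimal,
#'   infeasible, unbounded, iteration_limit, numerical_failure),
#'   `objective`, `z` (solution in original variables, or `NULL`),
#'   `iterations`, `wall_time` (seconds, diagnostic only), `backend`,
#'   `algorithm`.
#' @export
solve_lp <- function(lp, spec = solver_spec()) {
  stopifnot(inherits(lp, "lp_data"), inherits(spec, "solver_spec"))
  entry <- resolve_backend(spec)
  t0 <- proc.time()[["elapsed"]]
  res <- entry$fun(lp, tol = spec$tol, max_iter = spec$max_iter)
  wall <- proc.time()[["elapsed"]] - t0
  status <- res$status
  if (status == "optimal") {
    chk <- check_lp_solution(lp, res$z)
    feas_tol <- 10 * spec$tol *
      max(c(1, abs(lp$b_ub), abs(lp$ub[is.finite(lp$ub)])))
    if (chk$max_violation > feas_tol) status <- "numerical_failure"
  }
  structure(
    list(status = status,
         objective = if (status == "optimal") res$objective else NA_real_,
         z = if (status == "optimal") res$z else NULL,
         iterations = res$iterations, wall_time = wall,
         backend = entry$name, algorithm = entry$algorithm),
    class = "solve_report"
  )
}

#' @export
print.solve_report <- function(x, ...) {
  cat(sprintf("<solve_report> %s via %s (%s): objective %s in %d iterations (%.3fs)\n",
              x$status, x$backend, x$algorithm,
              if (is.na(x$objective)) "-" else format(x$objective),
              x$iterations, x$wall_time))
  invisible(x)
}

#' Extract the current pattern from a montage-LP solution
#'
#' @param lp The `lp_data` built by [build_l1l1_lp()].
#' @param report A `solve_report` with `status = "optimal"`.
#' @param labels Optional electrode labels.
#' @return A `current_pattern`: numeric vector of electrode currents (mA)
#'   with a `labels` attribute.
#' @export
extract_pattern <- function(lp, report, labels = NULL) {
  stopifnot(inherits(report, "solve_report"))
  if (report$status != "optimal") abort("no solution: status is not optimal.")
  y <- report$z[lp$layout$y]
  new_current_pattern(y, labels)
}

new_current_pattern <- function(y, labels = NULL) {
  structure(as.numeric(y), labels = labels, class = "current_pattern")
}

#' @export
print.current_pattern <- function(x, ...) {
  lab <- attr(x, "labels") %||% paste0("E", seq_along(x))
  active <- abs(x) > 0
  cat(sprintf("<current_pattern> %d channels, %d nonzero, sum %.2e mA, ||y||_1 = %.4g mA\n",
              length(x), sum(active), sum(x), sum(abs(x))))
  if (any(active)) {
    top <- order(abs(x), decreasing = TRUE)[seq_len(min(6, sum(active)))]
    cat("  ", paste(sprintf("%s %+0.3f", lab[top], x[top]), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Verify the montage safety constraints
#'
#' Checks zero net current, total dose, and per-channel cap for a current
#' pattern, each within a relative tolerance.
#'
#' @param y A current pattern (mA).
#' @param gamma Per-channel cap (mA).
#' @param mu Dose cap (mA).
#' @param tol Relative tolerance (default 1e-6).
#' @return `TRUE` if all three constraints hold, else `FALSE` (with the
#'   violations reported in the `"violations"` attribute).
#' @export
satisfies_safety <- function(y, gamma = 2.0, mu = 4.0, tol = 1e-6) {
  y <- as.numeric(y)
  v <- c(zero_sum = abs(sum(y)) - tol * mu,
         dose = sum(abs(y)) - mu * (1 + tol),
         channel = max(abs(y)) - gamma * (1 + tol))
  ok <- all(v <= 0)
  structure(ok, violations = pmax(v, 0))
}

#' Compare solver backends on a family of LPs
#'
#' Runs every spec on every instance and tabulates status, objective,
#' iteration count, and wall time. Pairs of optimal solves of the same
#' instance whose objectives disagree beyond `tol_rel` (relative) are
#' flagged; per-solve failures are recorded as rows, never aborting the
#' sweep.
#'
#' @param lp_family A list of `lp_data` instances.
#' @param specs A list of `solver_spec`s (at least one).
#' @param tol_rel Relative objective-agreement tolerance (default 1e-6).
#' @return A tibble with one row per (instance, spec) and a logical
#'   `disagrees` column.
#' @export
compare_backends <- function(lp_family, specs, tol_rel = 1e-6) {
  if (inherits(lp_family, "lp_data")) lp_family <- list(lp_family)
  if (inherits(specs, "solver_spec")) specs <- list(specs)
  if (length(specs) == 0L) abort("at least one solver spec is required.")
  rows <- list()
  for (i in seq_along(lp_family)) {
    reports <- lapply(specs, function(sp) {
      tryCatch(solve_lp(lp_family[[i]], sp),
               error = function(e) {
                 structure(list(status = "numerical_failure",
                                objective = NA_real_, z = NULL,
                                iterations = 0L, wall_time = NA_real_,
                                backend = sp$backend %||% NA_character_,
                                algorithm = sp$algorithm),
                           class = "solve_report")
               })
    })
    objs <- vapply(reports, function(r) r$objective, numeric(1))
    opt <- !is.na(objs)
    ref <- if (any(opt)) stats::median(objs[opt]) else NA_real_
    for (k in seq_along(reports)) {
      r <- reports[[k]]
      dis <- !is.na(objs[k]) && !is.na(ref) &&
        abs(objs[k] - ref) > tol_rel * max(1, abs(ref))
      rows[[length(rows) + 1L]] <- tibble(
        instance = i, backend = r$backend, algorithm = r$algorithm,
        status = r$status, objective = r$objective,
        iterations = r$iterations, wall_time = r$wall_time,
        disagrees = dis)
    }
  }
  dplyr::bind_rows(rows)
}
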