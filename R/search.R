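# Hyperparameter optimization over the (alpha, epsilon) plane.
#
# All three strategies operate in decibel coordinates (the lattice is
# logarithmic in the linear hyperparameters): exhaustive evaluation of a
# kappa x kappa Cartesian grid, derivative-free pattern (direct) search
# with window halving, and recursive grid renesting that re-lays a small
# grid over a shrinking sub-rectangle. Every evaluation is logged; the
# evaluation count is part of each method's contract (kappa^2, 1 + 4 polls,
# and levels * window^2 respectively).

#' Define the hyperparameter search space
#'
#' @param alpha_db_range Regularization-weight range in dB (default
#'   `c(-100, -20)`).
#' @param eps_db_range Nuisance-threshold range in dB (default
#'   `c(-160, 0)`; 0 dB is the upper bound 1 on the linear scale).
#' @param kappa Lattice size per axis for exhaustive search (default 15).
#' @return A `search_space` object.
#' @export
search_space <- function(alpha_db_range = c(-100, -20),
                         eps_db_range = c(-160, 0), kappa = 15L) {
  stopifnot(length(alpha_db_range) == 2L, length(eps_db_range) == 2L)
  if (alpha_db_range[1] >= alpha_db_range[2] ||
      eps_db_range[1] >= eps_db_range[2]) {
    abort("search-space ranges must satisfy low < high.")
  }
  kappa <- as.integer(kappa)
  if (kappa < 2L) abort("`kappa` must be at least 2.")
  structure(list(alpha_db_range = as.numeric(alpha_db_range),
                 eps_db_range = as.numeric(eps_db_range), kappa = kappa),
            class = "search_space")
}

#' Build a lattice evaluator for the montage problem
#'
#' Returns a closure `f(alpha_db, epsilon_db)` that converts the dB
#' coordinates to linear hyperparameters, solves the montage LP there, and
#' returns the one-row evaluation record. The closure keeps a running log
#' of every solve (including the optimal patterns) in its environment; the
#' searches read nothing from it, but the two-stage procedure uses the
#' stored patterns for electrode scoring.
#'
#' @param system A `focused_system`.
#' @param spec A `solver_spec`.
#' @param gamma,mu Safety limits (mA).
#' @param db_divisor 20 (amplitude dB convention, default) or 10.
#' @return A function; its call count is available via
#'   [evaluator_calls()], its pattern log via [evaluator_patterns()].
#' @export
l1l1_evaluator <- function(system, spec = solver_spec(), gamma = 2.0,
                           mu = 4.0, db_divisor = 20) {
  env <- new.env(parent = emptyenv())
  env$n_calls <- 0L
  env$patterns <- list()
  f <- function(alpha_db, epsilon_db) {
    cfg <- l1l1_config(alpha = db_to_linear(alpha_db, db_divisor),
                       epsilon = min(1, db_to_linear(epsilon_db, db_divisor)),
                       gamma = gamma, mu = mu)
    res <- solve_at(system, cfg, spec, alpha_db = alpha_db,
                    epsilon_db = epsilon_db)
    env$n_calls <- env$n_calls + 1L
    env$patterns[env$n_calls] <- list(res$pattern)  # keep NULLs as slots
    res$record
  }
  attr(f, "env") <- env
  f
}

#' @rdname l1l1_evaluator
#' @param evaluator A function built by [l1l1_evaluator()].
#' @export
evaluator_calls <- function(evaluator) attr(evaluator, "env")$n_calls

#' @rdname l1l1_evaluator
#' @export
evaluator_patterns <- function(evaluator) attr(evaluator, "env")$patterns

#' Wrap a plain bivariate function as a lattice evaluator
#'
#' Used to drive the searches with analytic objectives (the value is
#' recorded as both the intensity and the focality of the evaluation).
#'
#' @param f A function of `(alpha_db, epsilon_db)` returning a number.
#' @return An evaluator closure.
#' @export
function_evaluator <- function(f) {
  function(alpha_db, epsilon_db) {
    v <- f(alpha_db, epsilon_db)
    tibble(alpha_db = alpha_db, epsilon_db = epsilon_db,
           alpha = db_to_linear(alpha_db), epsilon = db_to_linear(epsilon_db),
           gamma_metric = v, theta_metric = v, objective = NA_real_,
           nnz = NA_integer_, status = "optimal")
  }
}

new_lattice_result <- function(trace, method, space, gamma_floor,
                               extra = list()) {
  ok <- trace$status == "optimal"
  gamma_max <- NULL
  theta_max <- NULL
  if (any(ok)) {
    gi <- which(ok)[which.max(trace$gamma_metric[ok])]
    gamma_max <- trace[gi, ]
    pass <- ok & is.finite(trace$theta_metric) &
      (if (is.null(gamma_floor)) TRUE else trace$gamma_metric >= gamma_floor)
    # exactly null-space montages (Theta = Inf) also qualify when they pass
    pass_inf <- ok & is.infinite(trace$theta_metric) & trace$theta_metric > 0 &
      (if (is.null(gamma_floor)) TRUE else trace$gamma_metric >= gamma_floor)
    pass <- pass | pass_inf
    if (any(pass)) {
      ti <- which(pass)[which.max(trace$theta_metric[pass])]
      theta_max <- trace[ti, ]
    }
  }
  structure(list(trace = trace, evaluation_count = nrow(trace),
                 gamma_maximizer = gamma_max, theta_maximizer = theta_max,
                 gamma_floor = gamma_floor, method = method, space = space,
                 deviation = list(gamma = NA_real_, theta = NA_real_),
                 extra = extra),
            class = "lattice_result")
}

#' @export
print.lattice_result <- function(x, ...) {
  cat(sprintf("<lattice_result> %s search, %d evaluations\n",
              x$method, x$evaluation_count))
  if (!is.null(x$gamma_maximizer)) {
    cat(sprintf("  Gamma_max = %.4g at (%.1f, %.1f) dB\n",
                x$gamma_maximizer$gamma_metric, x$gamma_maximizer$alpha_db,
                x$gamma_maximizer$epsilon_db))
  } else {
    cat("  no feasible evaluation found\n")
  }
  if (!is.null(x$theta_maximizer)) {
    cat(sprintf("  Theta_max = %.4g at (%.1f, %.1f) dB (floor %.4g)\n",
                x$theta_maximizer$theta_metric, x$theta_maximizer$alpha_db,
                x$theta_maximizer$epsilon_db, x$gamma_floor %||% NA))
  } else if (!is.null(x$gamma_floor)) {
    cat("  no evaluation passed the intensity floor\n")
  }
  invisible(x)
}

eval_grid <- function(evaluator, alphas, epss, level = NA_integer_) {
  rows <- vector("list", length(alphas) * length(epss))
  k <- 0L
  for (e in epss) {
    for (a in alphas) {
      k <- k + 1L
      rec <- evaluator(a, e)
      rec$level <- level
      rows[[k]] <- rec
    }
  }
  dplyr::bind_rows(rows)
}

#' Exhaustive lattice search
#'
#' Evaluates every point of the `kappa x kappa` Cartesian lattice (linear
#' spacing in dB on each axis, endpoints included) and records the
#' intensity and focality maximizers; the focality maximizer is restricted
#' to evaluations whose intensity reaches `gamma_floor` when one is given.
#' Second-order lattice-deviation estimates for both maximizers are
#' attached via [taylor_deviation()].
#'
#' @param space A `search_space`.
#' @param evaluator An evaluator closure (see [l1l1_evaluator()]).
#' @param gamma_floor Optional metacriterion floor `Gamma_0`.
#' @return A `lattice_result`; `evaluation_count` equals `kappa^2`.
#' @export
exhaustive_search <- function(space, evaluator, gamma_floor = NULL) {
  stopifnot(inherits(space, "search_space"))
  alphas <- seq(space$alpha_db_range[1], space$alpha_db_range[2],
                length.out = space$kappa)
  epss <- seq(space$eps_db_range[1], space$eps_db_range[2],
              length.out = space$kappa)
  trace <- eval_grid(evaluator, alphas, epss, level = 1L)
  res <- new_lattice_result(trace, "exhaustive", space, gamma_floor,
                            extra = list(alphas = alphas, epss = epss))
  res$deviation <- suppressWarnings(
    list(gamma = taylor_deviation(res, "gamma"),
         theta = taylor_deviation(res, "theta")))
  res
}

search_score <- function(trace, objective, gamma_floor) {
  s <- if (objective == "theta") trace$theta_metric else trace$gamma_metric
  s[trace$status != "optimal"] <- -Inf
  s[is.na(s)] <- -Inf
  if (objective == "theta" && !is.null(gamma_floor)) {
    s[!(trace$gamma_metric >= gamma_floor) %in% TRUE] <- -Inf
  }
  s
}

#' Direct (pattern) search over the hyperparameter plane
#'
#' Generalized pattern search: starting from a pivot (default the center
#' of the space), each iteration polls the four orthogonal neighbors at
#' per-axis window distances `(w_alpha, w_eps)` (clipped to the space) and
#' moves to the best strictly improving neighbor; when none improves, both
#' windows are halved. The search stops when both windows fall below
#' `min_window` or after `max_iter` polls.
#'
#' @inheritParams exhaustive_search
#' @param objective `"gamma"` (intensity, default) or `"theta"` (focality,
#'   subject to the floor).
#' @param initial Optional `c(alpha_db, epsilon_db)` start (default:
#'   center).
#' @param window Optional initial per-axis window (default: half the axis
#'   range).
#' @param min_window Optional per-axis stopping window (default: axis
#'   range / 256).
#' @param max_iter Poll cap (default 60).
#' @return A `lattice_result`; `evaluation_count = 1 + 4 * polls`.
#' @export
direct_search <- function(space, evaluator, objective = c("gamma", "theta"),
                          gamma_floor = NULL, initial = NULL, window = NULL,
                          min_window = NULL, max_iter = 60L) {
  stopifnot(inherits(space, "search_space"))
  objective <- match.arg(objective)
  ar <- space$alpha_db_range; er <- space$eps_db_range
  pivot <- initial %||% c(mean(ar), mean(er))
  if (pivot[1] < ar[1] || pivot[1] > ar[2] ||
      pivot[2] < er[1] || pivot[2] > er[2]) {
    abort("`initial` must lie inside the search space.")
  }
  w <- window %||% c((ar[2] - ar[1]) / 2, (er[2] - er[1]) / 2)
  if (length(w) == 1L) w <- c(w, w)
  wmin <- min_window %||% c((ar[2] - ar[1]) / 256, (er[2] - er[1]) / 256)
  if (length(wmin) == 1L) wmin <- c(wmin, wmin)

  clip <- function(p) c(min(max(p[1], ar[1]), ar[2]),
                        min(max(p[2], er[1]), er[2]))
  trace <- evaluator(pivot[1], pivot[2])
  trace$level <- 0L
  best <- search_score(trace, objective, gamma_floor)[1]
  polls <- 0L
  while (polls < max_iter && (w[1] >= wmin[1] || w[2] >= wmin[2])) {
    polls <- polls + 1L
    nbrs <- list(clip(pivot + c(w[1], 0)), clip(pivot - c(w[1], 0)),
                 clip(pivot + c(0, w[2])), clip(pivot - c(0, w[2])))
    recs <- dplyr::bind_rows(lapply(nbrs, function(p) evaluator(p[1], p[2])))
    recs$level <- polls
    trace <- dplyr::bind_rows(trace, recs)
    sc <- search_score(recs, objective, gamma_floor)
    if (any(is.finite(sc)) && max(sc) > best) {
      k <- which.max(sc)
      pivot <- unlist(nbrs[[k]])
      best <- max(sc)
    } else {
      w <- w / 2
    }
  }
  res <- new_lattice_result(trace, "direct", space, gamma_floor,
                            extra = list(pivot = pivot, final_window = w,
                                         polls = polls,
                                         objective = objective))
  res
}

#' Recursive grid-refinement search
#'
#' Lays a `window x window` dB grid over the full space, then repeatedly
#' re-grids a sub-rectangle centered on the incumbent best whose per-axis
#' half-width equals one grid step of the previous level (clipped to the
#' original space). All `window^2` points are evaluated at every level, so
#' the workload is `levels * window^2` in place of the exhaustive
#' `kappa^2`.
#'
#' @inheritParams direct_search
#' @param window Grid points per axis per level (`>= 2`).
#' @param levels Number of refinement levels (`>= 1`).
#' @return A `lattice_result`; `evaluation_count = levels * window^2`,
#'   and with `levels = 1` the evaluated point set is identical to
#'   [exhaustive_search()] with `kappa = window`.
#' @export
recursive_search <- function(space, evaluator, window = 3L, levels = 3L,
                             objective = c("gamma", "theta"),
                             gamma_floor = NULL) {
  stopifnot(inherits(space, "search_space"))
  objective <- match.arg(objective)
  window <- as.integer(window); levels <- as.integer(levels)
  if (window < 2L) abort("`window` must be at least 2.")
  if (levels < 1L) abort("`levels` must be at least 1.")
  ar <- space$alpha_db_range; er <- space$eps_db_range
  lo <- c(ar[1], er[1]); hi <- c(ar[2], er[2])
  trace <- NULL
  alphas <- epss <- NULL
  for (lev in seq_len(levels)) {
    alphas <- seq(lo[1], hi[1], length.out = window)
    epss <- seq(lo[2], hi[2], length.out = window)
    tr <- eval_grid(evaluator, alphas, epss, level = lev)
    trace <- dplyr::bind_rows(trace, tr)
    if (lev == levels) break
    sc <- search_score(trace, objective, gamma_floor)
    if (!any(is.finite(sc))) sc <- search_score(trace, "gamma", NULL)
    if (!any(is.finite(sc))) break
    k <- which.max(sc)
    center <- c(trace$alpha_db[k], trace$epsilon_db[k])
    step <- c(diff(range(alphas)), diff(range(epss))) / (window - 1)
    lo <- pmax(c(ar[1], er[1]), center - step)
    hi <- pmin(c(ar[2], er[2]), center + step)
  }
  res <- new_lattice_result(trace, "recursive", space, gamma_floor,
                            extra = list(window = window, levels = levels,
                                         final_alphas = alphas,
                                         final_epss = epss,
                                         objective = objective))
  res$deviation <- suppressWarnings(
    list(gamma = taylor_deviation(res, "gamma"),
         theta = taylor_deviation(res, "theta")))
  res
}
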