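# Lattice-deviation estimate: how much the maximizer value could move on a
# lattice of twice the resolution. A second-order Taylor polynomial is
# fitted at the maximizer from finite differences on the lattice, and the
# deviation is the largest |g'd + d'Hd/2| over the four half-step corner
# offsets d in {+-h_alpha/2} x {+-h_eps/2} — the half-cell the true
# optimum could hide in.

grid_taylor_deviation <- function(FF, i, j, h_a, h_e) {
  n_a <- nrow(FF); n_e <- ncol(FF)
  one_sided <- FALSE
  at <- function(ii, jj) FF[min(max(ii, 1L), n_a), min(max(jj, 1L), n_e)]

  if (i > 1L && i < n_a) {
    g_a <- (at(i + 1L, j) - at(i - 1L, j)) / (2 * h_a)
    h_aa <- (at(i + 1L, j) - 2 * at(i, j) + at(i - 1L, j)) / h_a^2
  } else {
    one_sided <- TRUE
    s <- if (i == 1L) 1L else -1L
    g_a <- s * (at(i + s, j) - at(i, j)) / h_a
    h_aa <- if (n_a >= 3L) {
      (at(i + 2L * s, j) - 2 * at(i + s, j) + at(i, j)) / h_a^2
    } else 0
  }
  if (j > 1L && j < n_e) {
    g_e <- (at(i, j + 1L) - at(i, j - 1L)) / (2 * h_e)
    h_ee <- (at(i, j + 1L) - 2 * at(i, j) + at(i, j - 1L)) / h_e^2
  } else {
    one_sided <- TRUE
    s <- if (j == 1L) 1L else -1L
    g_e <- s * (at(i, j + s) - at(i, j)) / h_e
    h_ee <- if (n_e >= 3L) {
      (at(i, j + 2L * s) - 2 * at(i, j + s) + at(i, j)) / h_e^2
    } else 0
  }
  si <- if (i == n_a) -1L else 1L
  sj <- if (j == n_e) -1L else 1L
  ia <- if (i > 1L && i < n_a) c(i - 1L, i + 1L) else c(i, i + si)
  je <- if (j > 1L && j < n_e) c(j - 1L, j + 1L) else c(j, j + sj)
  h_ae <- (at(ia[2], je[2]) - at(ia[2], je[1]) -
             at(ia[1], je[2]) + at(ia[1], je[1])) /
    ((diff(ia)) * h_a * (diff(je)) * h_e)

  dev <- 0
  for (da in c(-h_a / 2, h_a / 2)) {
    for (de in c(-h_e / 2, h_e / 2)) {
      v <- g_a * da + g_e * de +
        0.5 * (h_aa * da^2 + 2 * h_ae * da * de + h_ee * de^2)
      dev <- max(dev, abs(v))
    }
  }
  if (one_sided) {
    warn("lattice maximizer lies on the boundary; one-sided Taylor estimate.")
  }
  dev
}

#' Lattice-deviation estimate at a search maximizer
#'
#' Estimates, via a second-order Taylor polynomial fitted by finite
#' differences on the evaluation lattice, the maximum deviation of the
#' surface within half a lattice step of the maximizer — the value change
#' a lattice of twice the resolution could reveal. Defined for grid-based
#' results (exhaustive search, and the final level of recursive search);
#' pattern-search results return `NA`.
#'
#' @param lattice A `lattice_result`.
#' @param metric `"gamma"` (intensity surface) or `"theta"` (focality
#'   surface).
#' @return A non-negative number, or `NA` when no grid or maximizer is
#'   available.
#' @export
taylor_deviation <- function(lattice, metric = c("gamma", "theta")) {
  stopifnot(inherits(lattice, "lattice_result"))
  metric <- match.arg(metric)
  maxim <- if (metric == "gamma") lattice$gamma_maximizer else lattice$theta_maximizer
  if (is.null(maxim)) return(NA_real_)
  if (lattice$method == "exhaustive") {
    alphas <- lattice$extra$alphas; epss <- lattice$extra$epss
    sub <- lattice$trace
  } else if (lattice$method == "recursive") {
    alphas <- lattice$extra$final_alphas; epss <- lattice$extra$final_epss
    sub <- lattice$trace[lattice$trace$level == max(lattice$trace$level), ]
    # the maximizer may come from an earlier level; estimate only when it
    # sits on the final grid
    on_grid <- any(abs(alphas - maxim$alpha_db) < 1e-9) &&
      any(abs(epss - maxim$epsilon_db) < 1e-9)
    if (!on_grid) return(NA_real_)
  } else {
    return(NA_real_)
  }
  col <- if (metric == "gamma") "gamma_metric" else "theta_metric"
  FF <- matrix(NA_real_, length(alphas), length(epss))
  ia <- match(round(sub$alpha_db, 9), round(alphas, 9))
  je <- match(round(sub$epsilon_db, 9), round(epss, 9))
  FF[cbind(ia, je)] <- sub[[col]]
  i <- match(round(maxim$alpha_db, 9), round(alphas, 9))
  j <- match(round(maxim$epsilon_db, 9), round(epss, 9))
  # only the finite-difference stencil around the maximizer must be finite
  sten_i <- pmin(pmax(seq(i - 2L, i + 2L), 1L), nrow(FF))
  sten_j <- pmin(pmax(seq(j - 2L, j + 2L), 1L), ncol(FF))
  if (any(!is.finite(FF[sten_i, sten_j]))) return(NA_real_)
  h_a <- alphas[2] - alphas[1]
  h_e <- epss[2] - epss[1]
  grid_taylor_deviation(FF, i, j, h_a, h_e)
}
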