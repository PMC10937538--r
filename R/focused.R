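#' Specify the stimulation target
#'
#' A target is one or more lead-field nodes, a unit direction of desired
#' current flow per node, and the target amplitude `||x1||_2` in A/m^2. The
#' default amplitude 3.85 A/m^2 approximates the excitation current-density
#' threshold of motor-cortex nerve fibers.
#'
#' @param node_indices Non-empty integer vector of target node indices
#'   (1-based, unique).
#' @param direction A unit 3-vector, or a `T x 3` matrix of per-node unit
#'   directions.
#' @param amplitude Target amplitude `||x1||_2` in A/m^2 (default 3.85).
#' @return A `target_spec` object.
#' @examples
#' target_spec(5, c(0, 0, 1))
#' @export
target_spec <- function(node_indices, direction, amplitude = 3.85) {
  node_indices <- as.integer(node_indices)
  if (length(node_indices) == 0L || anyNA(node_indices)) {
    abort("`node_indices` must be a non-empty integer vector.")
  }
  if (anyDuplicated(node_indices)) abort("target node indices must be unique.")
  check_scalar(amplitude, "amplitude", 0, Inf, allow_equal = FALSE)
  dir <- direction
  if (is.null(dim(dir))) dir <- matrix(dir, nrow = 1L)
  dir <- as.matrix(dir)
  if (ncol(dir) != 3L) abort("`direction` must have 3 columns.")
  if (nrow(dir) == 1L && length(node_indices) > 1L) {
    dir <- dir[rep(1L, length(node_indices)), , drop = FALSE]
  }
  if (nrow(dir) != length(node_indices)) {
    abort("one direction per target node is required.")
  }
  nrm <- sqrt(rowSums(dir^2))
  if (any(nrm < 1e-12)) abort("zero-norm target direction.")
  if (any(abs(nrm - 1) > 1e-9)) {
    abort("target directions must be unit vectors (|d| = 1 within 1e-9).")
  }
  structure(list(node_indices = node_indices, direction = dir,
                 amplitude = amplitude),
            class = "target_spec")
}

# Orthonormal tangential pair completing unit vector d to a basis.
tangential_basis <- function(d) {
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  t1 <- ref - sum(ref * d) * d
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(d[2] * t1[3] - d[3] * t1[2],
          d[3] * t1[1] - d[1] * t1[3],
          d[1] * t1[2] - d[2] * t1[1])
  rbind(t1, t2)
}

#' Split a lead field into focused and nuisance blocks
#'
#' Projects each target node's three Cartesian rows onto the target
#' direction to form the focused block `L1` (one row per target node) and
#' collects every remaining field component into the nuisance block `L2`.
#' The two tangential components at each target node are part of the
#' nuisance block: only current along the prescribed direction is "focused",
#' and off-direction flow at the target is as undesirable as flow elsewhere.
#' The right-hand side is `x1 = amplitude * u` with equal per-target weights
#' `u` (`||x1||_2` equals the amplitude), and the scalings are
#' `zeta = ||L||_1` (maximum absolute column sum of the stacked system) and
#' `nu = ||x||_inf = max(|x1|)`.
#'
#' @param lead_field A `lead_field`.
#' @param target A `target_spec` valid for it.
#' @return A `focused_system` with fields `L1` (T x L), `L2` (M x L), `x1`,
#'   `zeta`, `nu`, `row_provenance` (tibble mapping each `L2` row to its
#'   node and component), and the originating `lead_field` / `target`.
#' @examples
#' lf <- generate_sphere_leadfield(8, 5, seed = 1)
#' sys <- build_focused_system(lf, target_spec(1, c(0, 0, 1)))
#' nrow(sys$L2)  # 3 * 5 - 1 = 14
#' @export
build_focused_system <- function(lead_field, target) {
  stopifnot(inherits(lead_field, "lead_field"), inherits(target, "target_spec"))
  P <- n_nodes(lead_field)
  L <- n_electrodes(lead_field)
  if (any(target$node_indices > P)) {
    abort("target node index out of range for this lead field.")
  }
  Tn <- length(target$node_indices)

  L1 <- matrix(0, Tn, L)
  tang_rows <- vector("list", Tn)
  tang_prov <- vector("list", Tn)
  for (k in seq_len(Tn)) {
    p <- target$node_indices[k]
    block <- lead_field$matrix[(3L * (p - 1L) + 1L):(3L * p), , drop = FALSE]
    d <- target$direction[k, ]
    L1[k, ] <- as.vector(d %*% block)
    tb <- tangential_basis(d)
    tang_rows[[k]] <- tb %*% block
    tang_prov[[k]] <- tibble(node = p, component = c("tangential1", "tangential2"))
  }

  keep <- setdiff(seq_len(P), target$node_indices)
  if (length(keep) > 0L) {
    ridx <- as.vector(vapply(keep, function(p) (3L * (p - 1L) + 1L):(3L * p),
                             integer(3)))
    L2_cart <- lead_field$matrix[ridx, , drop = FALSE]
    cart_prov <- tibble(node = rep(keep, each = 3L),
                        component = rep(c("x", "y", "z"), length(keep)))
  } else {
    L2_cart <- matrix(0, 0L, L)
    cart_prov <- tibble(node = integer(), component = character())
  }
  L2 <- rbind(do.call(rbind, tang_rows), L2_cart)
  provenance <- dplyr::bind_rows(dplyr::bind_rows(tang_prov), cart_prov)

  if (nrow(L2) == 0L) {
    warn("focused system has an empty nuisance block (M = 0).")
  }

  u <- rep(1 / sqrt(Tn), Tn)
  x1 <- target$amplitude * u
  zeta <- max(colSums(abs(rbind(L1, L2))))
  if (zeta <= 0) abort("degenerate lead field: ||L||_1 = 0.")
  nu <- max(abs(x1))

  structure(
    list(L1 = L1, L2 = L2, x1 = x1, zeta = zeta, nu = nu,
         row_provenance = provenance,
         electrode_labels = lead_field$electrode_labels,
         lead_field = lead_field, target = target),
    class = "focused_system"
  )
}

#' @export
print.focused_system <- function(x, ...) {
  cat(sprintf("<focused_system> T = %d target row(s), M = %d nuisance rows, L = %d electrodes\n",
              nrow(x$L1), nrow(x$L2), ncol(x$L1)))
  cat(sprintf("  ||x1||_2 = %.4g A/m^2, zeta = %.4g, nu = %.4g\n",
              sqrt(sum(x$x1^2)), x$zeta, x$nu))
  invisible(x)
}

#' Restrict a focused system to a subset of electrodes
#'
#' @param system A `focused_system`.
#' @param electrodes Indices or labels of electrodes to keep.
#' @return A `focused_system` over the restricted lead field.
#' @export
restrict_system <- function(system, electrodes) {
  stopifnot(inherits(system, "focused_system"))
  build_focused_system(restrict_leadfield(system$lead_field, electrodes),
                       system$target)
}
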