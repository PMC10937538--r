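# Synthetic spherical-head forward model.
#
# The generator stands in for a finite-element lead field: a smooth,
# distance-decaying linear map from electrode currents (mA) to the
# discretized volume current density (A/m^2) at nodes inside the head.
# Each electrode contributes a homogeneous-medium point-monopole kernel
#   J(p; e) = (p - e) / (4 pi |p - e|^3),
# scaled by one global constant; zero-net-current patterns cancel the
# common mode, so no boundary-correction terms are included.

# Global kernel scale: fixed so that the reciprocity bipolar intensity of
# the default mid-depth occipital target is of the order 0.1 A/m^2 at the
# 4 mA dose (the scale realistic head models produce near threshold).
KERNEL_SCALE <- 0.65

monopole_kernel <- function(p, e) {
  d <- p - e
  r <- sqrt(sum(d^2))
  d / (4 * pi * r^3)
}

#' Generate a synthetic spherical-head tES lead field
#'
#' Builds an `N x L` lead field matrix (`N = 3 * n_nodes` rows, three
#' Cartesian field components per node) for electrodes placed from the
#' built-in 10-10 table on the unit sphere and field nodes sampled
#' quasi-uniformly in the concentric ball of radius `inner_radius`
#' (the "brain" compartment). Column `l` holds, per node, the point-monopole
#' current-density kernel of electrode `l` times a fixed global scale; the
#' map is linear in the injected currents and deterministic for a fixed
#' `seed`.
#'
#' Defaults mirror a realistic desk study: a 128-channel 10-10 cap and 563
#' field nodes distributed through the brain compartment.
#'
#' @param n_electrodes Number of electrodes (2 to 128, from the built-in
#'   10-10 table).
#' @param n_nodes Number of field nodes (`>= 1`).
#' @param inner_radius Radius of the node-carrying ball as a fraction of the
#'   head radius, strictly between 0 and 1 (default 0.82).
#' @param seed Integer seed controlling node placement.
#' @param electrode_positions Optional `L x 3` matrix of unit-sphere
#'   electrode positions overriding the built-in table (rows are labelled
#'   `E1...EL` unless `electrode_labels` is given).
#' @param electrode_labels Optional character vector of electrode labels.
#' @return A `lead_field` object: a list with `matrix` (N x L, A/m^2 per
#'   mA), `electrode_labels`, `electrode_positions` (L x 3),
#'   `node_positions` (P x 3), `inner_radius`, `seed`, and the fixed
#'   component layout ("3 consecutive rows per node, Cartesian x,y,z").
#' @examples
#' lf <- generate_sphere_leadfield(8, 10, seed = 1)
#' dim(lf$matrix)  # 30 x 8
#' @export
generate_sphere_leadfield <- function(n_electrodes = 128L, n_nodes = 563L,
                                      inner_radius = 0.82, seed = 1L,
                                      electrode_positions = NULL,
                                      electrode_labels = NULL) {
  check_scalar(inner_radius, "inner_radius", 0, 1, allow_equal = FALSE)
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 1L) abort("`n_nodes` must be at least 1.")

  if (is.null(electrode_positions)) {
    cap <- ten_ten_cap(n_electrodes)
    epos <- as.matrix(cap[, c("x", "y", "z")])
    elab <- cap$label
  } else {
    epos <- as.matrix(electrode_positions)
    if (ncol(epos) != 3L || nrow(epos) < 2L) {
      abort("`electrode_positions` must be an L x 3 matrix with L >= 2.")
    }
    nrm <- sqrt(rowSums(epos^2))
    if (any(abs(nrm - 1) > 1e-9)) {
      abort("electrode positions must lie on the unit sphere (|pos| = 1).")
    }
    elab <- electrode_labels %||% paste0("E", seq_len(nrow(epos)))
  }
  L <- nrow(epos)

  npos <- with_private_seed(seed, {
    sample_ball_nodes(n_nodes, inner_radius, epos)
  })

  mat <- matrix(0, nrow = 3L * n_nodes, ncol = L)
  for (l in seq_len(L)) {
    d <- sweep(npos, 2, epos[l, ])            # P x 3 displacement
    r3 <- (rowSums(d^2))^1.5
    mat[, l] <- as.vector(t(d / (4 * pi * r3)))
  }
  mat <- KERNEL_SCALE * mat
  dimnames(mat) <- list(NULL, elab)

  new_lead_field(mat, elab, epos, npos, inner_radius, as.integer(seed))
}

# Quasi-uniform sampling of the ball of radius `radius`: uniform density via
# the r ~ u^{1/3} radial law; nodes falling within 0.02 head radii of an
# electrode are rejected and resampled (degenerate kernel guard).
sample_ball_nodes <- function(n_nodes, radius, epos, min_clearance = 0.02) {
  out <- matrix(NA_real_, n_nodes, 3L)
  filled <- 0L
  attempts <- 0L
  while (filled < n_nodes) {
    attempts <- attempts + 1L
    if (attempts > 1000L * n_nodes) {
      abort("node sampling failed: cannot place nodes clear of electrodes.")
    }
    dir <- stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    r <- radius * stats::runif(1)^(1 / 3)
    p <- r * dir
    dmin <- min(sqrt(rowSums(sweep(epos, 2, p)^2)))
    if (dmin < min_clearance) next
    filled <- filled + 1L
    out[filled, ] <- p
  }
  out
}

new_lead_field <- function(mat, labels, epos, npos, inner_radius, seed) {
  lf <- structure(
    list(matrix = mat,
         electrode_labels = labels,
         electrode_positions = epos,
         node_positions = npos,
         inner_radius = inner_radius,
         seed = seed,
         component_layout = "3 consecutive rows per node, Cartesian x,y,z"),
    class = "lead_field"
  )
  validate_lead_field(lf)
  lf
}

validate_lead_field <- function(lf) {
  m <- lf$matrix
  P <- nrow(lf$node_positions)
  L <- ncol(m)
  if (nrow(m) != 3L * P) abort("lead field must have 3 rows per node.")
  if (L < 2L) abort("lead field needs at least 2 electrodes.")
  if (!all(is.finite(m))) abort("lead field contains non-finite entries.")
  if (length(lf$electrode_labels) != L) {
    abort("electrode label count does not match the number of columns.")
  }
  enrm <- sqrt(rowSums(lf$electrode_positions^2))
  if (any(abs(enrm - 1) > 1e-9)) {
    abort("electrode positions must have unit norm.")
  }
  nnrm <- sqrt(rowSums(lf$node_positions^2))
  if (any(nnrm > lf$inner_radius + 1e-9)) {
    abort("node positions must lie inside the inner-radius ball.")
  }
  invisible(lf)
}

#' @export
print.lead_field <- function(x, ...) {
  cat(sprintf("<lead_field> %d nodes x 3 components (N = %d rows), %d electrodes\n",
              nrow(x$node_positions), nrow(x$matrix), ncol(x$matrix)))
  cat(sprintf("  inner radius %.2f, seed %d, units A/m^2 per mA\n",
              x$inner_radius, x$seed))
  invisible(x)
}

#' Number of electrodes / nodes of a lead field
#' @param lf A `lead_field`.
#' @return An integer.
#' @export
n_electrodes <- function(lf) ncol(lf$matrix)

#' @rdname n_electrodes
#' @export
n_nodes <- function(lf) nrow(lf$node_positions)

#' Restrict a lead field to a subset of electrodes
#'
#' Keeps the given electrode columns (used by the second stage of the
#' two-stage procedure, which re-optimizes over the retained channels only).
#'
#' @param lf A `lead_field`.
#' @param electrodes Integer indices or labels of electrodes to keep.
#' @return A `lead_field` with `length(electrodes)` columns.
#' @export
restrict_leadfield <- function(lf, electrodes) {
  if (is.character(electrodes)) {
    electrodes <- match(electrodes, lf$electrode_labels)
  }
  electrodes <- as.integer(electrodes)
  if (anyNA(electrodes) || any(electrodes < 1L | electrodes > n_electrodes(lf))) {
    abort("unknown electrode selection.")
  }
  if (length(electrodes) < 2L) abort("at least 2 electrodes must remain.")
  new_lead_field(lf$matrix[, electrodes, drop = FALSE],
                 lf$electrode_labels[electrodes],
                 lf$electrode_positions[electrodes, , drop = FALSE],
                 lf$node_positions, lf$inner_radius, lf$seed)
}
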