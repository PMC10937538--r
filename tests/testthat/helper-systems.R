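# Shared fixtures: all built in code at test time.

# Small seeded head-model system.
make_system <- function(L = 8L, P = 6L, seed = 1L, node = 1L,
                        dir = c(0, 0, 1), amplitude = 3.85) {
  lf <- generate_sphere_leadfield(L, P, seed = seed)
  build_focused_system(lf, target_spec(node, dir, amplitude = amplitude))
}

# Hand-built focused system with explicit blocks (bypasses the head model);
# used for arithmetic oracles where the blocks must be exact.
make_toy_system <- function(L1, L2 = NULL, amplitude = 3.85) {
  L1 <- rbind(L1)
  if (is.null(L2)) L2 <- matrix(0, 0, ncol(L1))
  L2 <- rbind(L2)
  Tn <- nrow(L1)
  x1 <- amplitude * rep(1 / sqrt(Tn), Tn)
  structure(
    list(L1 = L1, L2 = L2, x1 = x1,
         zeta = max(colSums(abs(rbind(L1, L2)))),
         nu = max(abs(x1)),
         row_provenance = tibble::tibble(node = integer(), component = character()),
         electrode_labels = paste0("E", seq_len(ncol(L1))),
         lead_field = NULL, target = NULL),
    class = "focused_system")
}

# LP that maximizes b'y over the montage safety set
# {sum(y) = 0, ||y||_1 <= mu, |y| <= gamma}; the independent oracle for the
# reciprocity maximizer (variables [y, u] with u the |y| majorants).
intensity_lp <- function(b, mu = 4.0, gamma = 2.0) {
  L <- length(b)
  A_ub <- rbind(cbind(diag(L), -diag(L)),
                cbind(-diag(L), -diag(L)),
                c(rep(0, L), rep(1, L)))
  tesmontage:::new_lp_data(
    c(-b, rep(0, L)), A_ub, c(rep(0, 2 * L), mu),
    matrix(c(rep(1, L), rep(0, L)), 1), 0,
    c(rep(-gamma, L), rep(0, L)), rep(gamma, 2 * L), NULL)
}

all_algorithms <- c("interior-point", "primal-simplex", "dual-simplex")
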