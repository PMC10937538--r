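# Reciprocity-principle reference maximizer.
#
# The intensity Gamma(y) = x1' L1 y / ||x1||_2 is a linear functional
# b' y of the montage, with b the back-projection of the target through the
# focused block. Over the safety set {sum(y) = 0, ||y||_1 <= mu,
# |y| <= gamma} (with gamma >= mu/2) the maximum is attained by the
# zero-sum bipolar pair +mu/2 at argmax(b), -mu/2 at argmin(b): the
# anode/cathode pair with the largest back-projected responses. The
# restricted-K montages y_K = mu * s_K of the classical formulation are
# kept as a diagnostic path; they do not in general sum to zero, which is
# why the reference maximizer enforces the bipolar zero-sum form.

#' Back-projection of the target through the lead field
#'
#' Computes `b = L1' x1 / ||x1||_2` (A/m^2 per mA per electrode). The
#' intensity of any montage is the inner product `Gamma(y) = b' y`.
#'
#' @param system A `focused_system`.
#' @return A named numeric vector of length L.
#' @export
back_projection <- function(system) {
  stopifnot(inherits(system, "focused_system"))
  b <- as.numeric(crossprod(system$L1, system$x1)) / sqrt(sum(system$x1^2))
  names(b) <- system$electrode_labels
  b
}

#' Restricted reciprocity montage over the top-K electrodes
#'
#' Orders electrodes by decreasing absolute back-projected response and
#' builds the classical restricted montage: `s_K` is the top-K
#' back-projection renormalized to unit L1 norm, `sigma_K = ||top-K of
#' L1' x1||_1 / ||x1||_2`, the montage is `y_K = mu * s_K`, and its
#' intensity is `Gamma_K = mu * sigma_K * ||s_K||_2^2`. Note that `y_K`
#' need not sum to zero for `K > 2`; it is a diagnostic, not a deliverable
#' montage.
#'
#' @param system A `focused_system`.
#' @param K Number of electrodes retained (1 to L).
#' @param mu Current dose (mA, default 4).
#' @return A list with `electrodes` (indices, ordered), `s_K`, `sigma_K`,
#'   `y_K`, and `gamma_K`.
#' @export
restricted_montage <- function(system, K, mu = 4.0) {
  b <- back_projection(system)
  L <- length(b)
  K <- as.integer(K)
  if (K < 1L || K > L) abort("`K` must be between 1 and L.")
  ord <- order(abs(b), decreasing = TRUE)
  idx <- ord[seq_len(K)]
  v <- b[idx] * sqrt(sum(system$x1^2))   # R_K' L1' x1 on the retained set
  if (sum(abs(v)) == 0) abort("degenerate target: zero back-projection on the top-K set.")
  sigma_K <- sum(abs(v)) / sqrt(sum(system$x1^2))
  s_K <- as.numeric(v) / sum(abs(v))
  list(electrodes = idx, s_K = s_K, sigma_K = sigma_K,
       y_K = mu * s_K, gamma_K = mu * sigma_K * sum(s_K^2))
}

#' Bipolar reciprocity maximizer
#'
#' The zero-sum bipolar montage `+mu/2` at the electrode with the largest
#' back-projected response and `-mu/2` at the one with the smallest
#' (most negative), which maximizes the intensity `Gamma = b' y` over the
#' safety set when `gamma >= mu / 2`. When the two largest `|b|` entries
#' are opposite-signed (the typical dipolar target), this coincides with
#' taking the first two entries of the reciprocity ordering.
#'
#' @param system A `focused_system`.
#' @param mu Current dose (mA, default 4).
#' @param gamma Per-channel cap (mA, default 2); must satisfy
#'   `gamma >= mu / 2`.
#' @return A list with `pattern` (a `current_pattern`), `gamma_max`
#'   (A/m^2), the anode/cathode indices, and `degenerate` (`TRUE` when all
#'   back-projections are equal so no current helps).
#' @export
bipolar_maximizer <- function(system, mu = 4.0, gamma = 2.0) {
  if (gamma < mu / 2) {
    abort("bipolar maximizer requires gamma >= mu / 2.")
  }
  b <- back_projection(system)
  i_an <- which.max(b)
  i_ca <- which.min(b)
  degenerate <- (b[i_an] - b[i_ca]) <= 0
  if (i_an == i_ca) i_ca <- if (i_an == 1L) 2L else 1L
  y <- numeric(length(b))
  y[i_an] <- mu / 2
  y[i_ca] <- -mu / 2
  gamma_max <- (mu / 2) * (b[i_an] - b[i_ca])
  list(pattern = new_current_pattern(y, system$electrode_labels),
       gamma_max = as.numeric(gamma_max),
       anode = unname(i_an), cathode = unname(i_ca),
       degenerate = unname(degenerate))
}

#' Full reciprocity report
#'
#' Back-projection ordering, the per-K restricted montages, and the bipolar
#' maximizer, collected for serialization.
#'
#' @inheritParams bipolar_maximizer
#' @param K_max Largest K tabulated (default `min(L, 10)`).
#' @return A `reciprocity_result` list with `ordering`, a per-K tibble
#'   (`K`, `sigma_K`, `s_norm2_sq`, `gamma_K`), and the bipolar maximizer.
#' @export
reciprocity_report <- function(system, mu = 4.0, gamma = 2.0,
                               K_max = NULL) {
  b <- back_projection(system)
  L <- length(b)
  K_max <- K_max %||% min(L, 10L)
  ord <- order(abs(b), decreasing = TRUE)
  per_k <- purrr::map_dfr(seq_len(K_max), function(K) {
    rm <- restricted_montage(system, K, mu = mu)
    tibble(K = K, sigma_K = rm$sigma_K, s_norm2_sq = sum(rm$s_K^2),
           gamma_K = rm$gamma_K)
  })
  bip <- bipolar_maximizer(system, mu = mu, gamma = gamma)
  structure(list(ordering = ord, back_projection = b, per_K = per_k,
                 bipolar = bip, mu = mu, gamma = gamma),
            class = "reciprocity_result")
}

#' @export
print.reciprocity_result <- function(x, ...) {
  lab <- names(x$back_projection)
  cat(sprintf("<reciprocity_result> bipolar %s (+%.2f mA) / %s (%.2f mA): Gamma_max = %.4g A/m^2\n",
              lab[x$bipolar$anode], x$mu / 2, lab[x$bipolar$cathode],
              -x$mu / 2, x$bipolar$gamma_max))
  invisible(x)
}
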