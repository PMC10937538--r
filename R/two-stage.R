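# Two-stage electrode-restriction procedure.
#
# Stage 1 searches the full cap and scores each electrode by the largest
# absolute current it carries across the metacriterion-passing lattice
# evaluations; the montage is filtered down to the top `n_active`
# electrodes (20 by default, the channel count of commercial multichannel
# stimulators) and the incumbent pattern is renormalized to the full dose.
# Stage 2 rebuilds the system over the retained electrodes only and re-runs
# the search with the final objective (intensity or focality), after which
# the winning pattern is thresholded to its non-zero channels.

run_search <- function(method, space, evaluator, objective, gamma_floor,
                       search_args = list()) {
  switch(method,
    exhaustive = exhaustive_search(space, evaluator,
                                   gamma_floor = gamma_floor),
    direct = do.call(direct_search,
                     c(list(space = space, evaluator = evaluator,
                            objective = objective,
                            gamma_floor = gamma_floor), search_args)),
    recursive = do.call(recursive_search,
                        c(list(space = space, evaluator = evaluator,
                               objective = objective,
                               gamma_floor = gamma_floor), search_args)),
    abort(sprintf("unknown search method '%s'.", method))
  )
}

best_record <- function(lattice, objective) {
  if (objective == "theta" && !is.null(lattice$theta_maximizer)) {
    return(lattice$theta_maximizer)
  }
  lattice$gamma_maximizer
}

# Zero sub-threshold channels, then restore an exactly zero net current by
# scaling each sign side down to the smaller side's total; scaling down can
# never violate the per-channel or dose caps.
threshold_pattern <- function(y, mu, threshold_fraction = 1e-3) {
  y <- as.numeric(y)
  active <- abs(y) > threshold_fraction * mu
  y[!active] <- 0
  pos <- sum(y[y > 0]); neg <- -sum(y[y < 0])
  if (pos <= 0 || neg <= 0) return(y * 0)
  s <- min(pos, neg)
  y[y > 0] <- y[y > 0] * s / pos
  y[y < 0] <- y[y < 0] * s / neg
  y
}

#' Two-stage montage optimization
#'
#' Runs the full pipeline: a stage-1 lattice search over all electrodes,
#' electrode scoring and restriction to the `n_active` most-contributing
#' channels, and a stage-2 search over the restricted cap with the final
#' objective, returning the thresholded montage.
#'
#' @param system A `focused_system` over the full electrode cap.
#' @param method Search method: `"recursive"` (default), `"exhaustive"`,
#'   or `"direct"`.
#' @param space A `search_space` (default: the standard dB ranges).
#' @param spec A `solver_spec`.
#' @param n_active Number of electrodes retained after stage 1 (default
#'   20, capped at L).
#' @param objective Stage-2 objective: `"gamma"` (intensity, default) or
#'   `"theta"` (focality under the intensity floor).
#' @param gamma,mu Safety limits (mA).
#' @param metacriterion_fraction Intensity-floor fraction of the bipolar
#'   maximum (default 0.75).
#' @param threshold_fraction Final non-zero-channel threshold as a
#'   fraction of `mu` (default 1e-3).
#' @param db_divisor dB convention switch (20, default, or 10).
#' @param search_args List of extra arguments for the search method (e.g.
#'   `window`, `levels` for recursive; `max_iter` for direct).
#' @return A `stage_outcome`: list with `stage1`, `stage2` (both
#'   `lattice_result`s), `electrode_scores`, `kept` (labels),
#'   `stage1_montage` (dose-normalized incumbent), `montage` (tibble
#'   `label`, `current_mA`, `active`), `final_pattern` (full-length
#'   `current_pattern`), `gamma_floor`, and the final `gamma`/`theta`/
#'   `nnz`.
#' @export
two_stage <- function(system, method = c("recursive", "exhaustive", "direct"),
                      space = search_space(), spec = solver_spec(),
                      n_active = 20L, objective = c("gamma", "theta"),
                      gamma = 2.0, mu = 4.0,
                      metacriterion_fraction = 0.75,
                      threshold_fraction = 1e-3, db_divisor = 20,
                      search_args = list()) {
  stopifnot(inherits(system, "focused_system"))
  method <- match.arg(method)
  objective <- match.arg(objective)
  L <- ncol(system$L1)
  n_active <- min(as.integer(n_active), L)
  if (n_active < 2L) abort("`n_active` must be at least 2.")

  floor0 <- metacriterion_floor(system, metacriterion_fraction,
                                mu = mu, gamma = gamma)

  ev1 <- l1l1_evaluator(system, spec, gamma = gamma, mu = mu,
                        db_divisor = db_divisor)
  stage1 <- run_search(method, space, ev1, objective = "gamma",
                       gamma_floor = floor0, search_args = search_args)
  pats <- evaluator_patterns(ev1)
  ok <- stage1$trace$status == "optimal"
  if (!any(ok)) abort("stage 1 found no feasible lattice point.")
  pass <- ok & (stage1$trace$gamma_metric >= floor0) %in% TRUE
  if (!any(pass)) {
    warn("no stage-1 evaluation passed the intensity floor; scoring over all feasible evaluations.")
    pass <- ok
  }
  pmat <- do.call(rbind, lapply(pats[pass], as.numeric))
  scores <- apply(abs(pmat), 2, max)
  if (sum(scores > 0) < 2L) {
    abort("degenerate stage-1 selection: fewer than 2 electrodes ever active.")
  }
  keep <- order(scores, decreasing = TRUE)[seq_len(n_active)]
  keep <- sort(keep)

  inc <- as.numeric(pats[[which(ok)[which.max(stage1$trace$gamma_metric[ok])]]])
  if (sum(abs(inc)) > 0) inc <- inc * mu / sum(abs(inc))
  stage1_montage <- new_current_pattern(inc, system$electrode_labels)

  sys2 <- restrict_system(system, keep)
  ev2 <- l1l1_evaluator(sys2, spec, gamma = gamma, mu = mu,
                        db_divisor = db_divisor)
  stage2 <- run_search(method, space, ev2, objective = objective,
                       gamma_floor = floor0, search_args = search_args)
  best2 <- best_record(stage2, objective)
  if (is.null(best2)) abort("stage 2 found no feasible lattice point.")
  pats2 <- evaluator_patterns(ev2)
  k2 <- which(stage2$trace$alpha_db == best2$alpha_db &
                stage2$trace$epsilon_db == best2$epsilon_db &
                stage2$trace$status == "optimal")[1]
  y2 <- threshold_pattern(as.numeric(pats2[[k2]]), mu = mu,
                          threshold_fraction = threshold_fraction)

  y_full <- numeric(L)
  y_full[keep] <- y2
  final <- new_current_pattern(y_full, system$electrode_labels)
  montage <- tibble(label = system$electrode_labels,
                    current_mA = y_full,
                    active = abs(y_full) > 0)

  structure(
    list(stage1 = stage1, stage2 = stage2,
         electrode_scores = setNames(scores, system$electrode_labels),
         kept = system$electrode_labels[keep], kept_idx = keep,
         stage1_montage = stage1_montage,
         montage = montage, final_pattern = final,
         gamma_floor = floor0, objective = objective,
         gamma = gamma_metric(system, y_full),
         theta = theta_metric(system, y_full),
         nnz = nnz_channels(y_full, mu = mu,
                            threshold_fraction = threshold_fraction),
         mu = mu, gamma_cap = gamma, method = method,
         restricted_system = sys2),
    class = "stage_outcome"
  )
}

#' @export
print.stage_outcome <- function(x, ...) {
  cat(sprintf("<stage_outcome> %s search, objective %s\n", x$method,
              x$objective))
  cat(sprintf("  kept %d electrodes; final montage: %d active channels\n",
              length(x$kept), x$nnz))
  cat(sprintf("  Gamma = %.4g A/m^2 (floor %.4g), Theta = %.4g\n",
              x$gamma, x$gamma_floor, x$theta))
  invisible(x)
}
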