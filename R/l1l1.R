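# Solving the montage problem at one hyperparameter point and scoring the
# result: intensity Gamma (projection of the achieved current density onto
# the target, A/m^2), focality Theta (Gamma over the RMS nuisance
# density), and the channel count of the montage.

#' Intensity of a montage
#'
#' `Gamma = x1' (L1 y) / ||x1||_2`, in A/m^2: the component of the achieved
#' current density along the target, normalized by the target norm.
#'
#' @param system A `focused_system`.
#' @param y Current pattern of length L (mA).
#' @return A number.
#' @export
gamma_metric <- function(system, y) {
  stopifnot(inherits(system, "focused_system"))
  y <- as.numeric(y)
  sum(system$x1 * as.numeric(system$L1 %*% y)) / sqrt(sum(system$x1^2))
}

#' Focality of a montage
#'
#' `Theta = Gamma / (||L2 y||_2 / sqrt(M))`: intensity relative to the
#' root-mean-square nuisance current density (dimensionless). A montage
#' with positive intensity and an exactly vanishing nuisance field returns
#' `Inf`; zero intensity with zero nuisance returns 0; an empty nuisance
#' block (`M = 0`) is undefined and returns `Inf` with a warning.
#'
#' @inheritParams gamma_metric
#' @return A number (possibly `Inf`).
#' @export
theta_metric <- function(system, y) {
  stopifnot(inherits(system, "focused_system"))
  y <- as.numeric(y)
  M <- nrow(system$L2)
  if (M == 0L) {
    warn("Theta is undefined for an empty nuisance block (M = 0).")
    return(Inf)
  }
  g <- gamma_metric(system, y)
  rms <- sqrt(sum(as.numeric(system$L2 %*% y)^2)) / sqrt(M)
  if (rms == 0) {
    if (g > 0) return(Inf)
    return(0)
  }
  g / rms
}

#' Count the non-zero channels of a montage
#'
#' Channels carrying more than `threshold_fraction * mu` of current, the
#' rule used to threshold the final two-stage montage.
#'
#' @param y Current pattern (mA).
#' @param mu Dose cap the threshold is relative to (mA, default 4).
#' @param threshold_fraction Fraction of `mu` below which a channel counts
#'   as off (default 1e-3; 0 counts exact nonzeros).
#' @return An integer.
#' @export
nnz_channels <- function(y, mu = 4.0, threshold_fraction = 1e-3) {
  check_scalar(threshold_fraction, "threshold_fraction", 0, 1,
               allow_equal = TRUE)
  if (threshold_fraction >= 1) abort("`threshold_fraction` must be < 1.")
  sum(abs(as.numeric(y)) > threshold_fraction * mu)
}

#' Intensity floor of the focality metacriterion
#'
#' `Gamma_0 = fraction * Gamma_max(bipolar)`: focality maximizers are only
#' accepted when they retain at least this intensity, preventing the
#' focality search from collapsing onto vanishing currents. The default
#' fraction is 0.75 of the bipolar reciprocity maximum.
#'
#' @param system A `focused_system`.
#' @param fraction Fraction of the bipolar maximum in (0, 1\] (default
#'   0.75).
#' @param mu,gamma Safety limits used for the bipolar reference.
#' @return A number (A/m^2).
#' @export
metacriterion_floor <- function(system, fraction = 0.75, mu = 4.0,
                                gamma = 2.0) {
  check_scalar(fraction, "fraction", 0, 1, allow_equal = TRUE)
  if (fraction <= 0) abort("`fraction` must be positive.")
  fraction * bipolar_maximizer(system, mu = mu, gamma = gamma)$gamma_max
}

#' Solve the montage problem at one hyperparameter point
#'
#' Builds the LP for the given `(alpha, epsilon)`, solves it with the
#' requested algorithm, and evaluates the montage: intensity, focality,
#' objective, and channel count. Solver failures are propagated in the
#' record's `status`, never as errors.
#'
#' @param system A `focused_system`.
#' @param config An `l1l1_config`.
#' @param spec A `solver_spec` (default interior point).
#' @param alpha_db,epsilon_db Optional dB coordinates recorded alongside
#'   the linear values (purely informational).
#' @return A list with `pattern` (a `current_pattern`, or `NULL` unless
#'   optimal) and `record`, a one-row tibble with `alpha_db`, `epsilon_db`,
#'   `alpha`, `epsilon`, `gamma_metric`, `theta_metric`, `objective`,
#'   `nnz`, `status`.
#' @examples
#' lf <- generate_sphere_leadfield(8, 6, seed = 3)
#' sys <- build_focused_system(lf, target_spec(2, c(0, 0, 1)))
#' solve_at(sys, l1l1_config(1e-3, 0.5))$record
#' @export
solve_at <- function(system, config, spec = solver_spec(),
                     alpha_db = NA_real_, epsilon_db = NA_real_) {
  stopifnot(inherits(system, "focused_system"), inherits(config, "l1l1_config"))
  lp <- build_l1l1_lp(system, config)
  report <- solve_lp(lp, spec)
  if (report$status == "optimal") {
    y <- extract_pattern(lp, report, labels = system$electrode_labels)
    rec <- tibble(
      alpha_db = alpha_db, epsilon_db = epsilon_db,
      alpha = config$alpha, epsilon = config$epsilon,
      gamma_metric = gamma_metric(system, y),
      theta_metric = theta_metric(system, y),
      objective = report$objective,
      nnz = nnz_channels(y, mu = config$mu),
      status = report$status)
  } else {
    y <- NULL
    rec <- tibble(
      alpha_db = alpha_db, epsilon_db = epsilon_db,
      alpha = config$alpha, epsilon = config$epsilon,
      gamma_metric = NA_real_, theta_metric = NA_real_,
      objective = NA_real_, nnz = NA_integer_, status = report$status)
  }
  list(pattern = y, record = rec, report = report)
}
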