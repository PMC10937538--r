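#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom stats setNames
NULL

# Run `expr` with a private RNG stream so package functions are deterministic
# for a given `seed` without disturbing the caller's RNG state.
with_private_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

#' Convert between decibel and linear hyperparameter values
#'
#' The lattice-search hyperparameters (the regularization weight and the
#' nuisance threshold) are expressed on a logarithmic decibel axis. The
#' package default is the amplitude convention `value = 10^(dB / 20)`, under
#' which the threshold range \[-160, 0\] dB maps onto \[1e-8, 1\]; the power
#' convention (divisor 10) is available as a switch.
#'
#' @param db,value Numeric vectors of decibel or linear values.
#' @param divisor Either 20 (amplitude convention, default) or 10 (power
#'   convention).
#' @return A numeric vector.
#' @examples
#' db_to_linear(0)     # 1
#' db_to_linear(-160)  # 1e-8
#' linear_to_db(0.1)   # -20
#' @export
db_to_linear <- function(db, divisor = 20) {
  stopifnot(divisor %in% c(10, 20))
  10^(db / divisor)
}

#' @rdname db_to_linear
#' @export
linear_to_db <- function(value, divisor = 20) {
  stopifnot(divisor %in% c(10, 20))
  divisor * log10(value)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         allow_equal = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  ok <- if (allow_equal) x >= lower && x <= upper else x > lower && x < upper
  if (!ok) {
    abort(sprintf("`%s` = %g is outside the allowed range [%g, %g].",
                  name, x, lower, upper))
  }
  invisible(x)
}

l1_norm <- function(x) sum(abs(x))
linf_norm <- function(x) max(abs(x))
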