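# broom-style accessors and ggplot2 autoplot methods for the result types.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a lattice search result
#'
#' @param x A `lattice_result`.
#' @param ... Unused.
#' @return The full evaluation trace as a tibble (one row per solver call).
#' @export
tidy.lattice_result <- function(x, ...) x$trace

#' @rdname tidy.lattice_result
#' @export
glance.lattice_result <- function(x, ...) {
  gm <- x$gamma_maximizer; tm <- x$theta_maximizer
  tibble(method = x$method, evaluations = x$evaluation_count,
         gamma_max = if (is.null(gm)) NA_real_ else gm$gamma_metric,
         gamma_alpha_db = if (is.null(gm)) NA_real_ else gm$alpha_db,
         gamma_eps_db = if (is.null(gm)) NA_real_ else gm$epsilon_db,
         theta_max = if (is.null(tm)) NA_real_ else tm$theta_metric,
         theta_alpha_db = if (is.null(tm)) NA_real_ else tm$alpha_db,
         theta_eps_db = if (is.null(tm)) NA_real_ else tm$epsilon_db,
         gamma_floor = x$gamma_floor %||% NA_real_,
         dev_gamma = x$deviation$gamma, dev_theta = x$deviation$theta,
         n_failed = sum(x$trace$status != "optimal"))
}

#' Tidy a two-stage outcome
#'
#' @param x A `stage_outcome`.
#' @param ... Unused.
#' @return The montage tibble (`label`, `current_mA`, `active`).
#' @export
tidy.stage_outcome <- function(x, ...) x$montage

#' @rdname tidy.stage_outcome
#' @export
glance.stage_outcome <- function(x, ...) {
  tibble(method = x$method, objective = x$objective,
         gamma = x$gamma, theta = x$theta, nnz = x$nnz,
         gamma_floor = x$gamma_floor, n_kept = length(x$kept),
         stage1_evaluations = x$stage1$evaluation_count,
         stage2_evaluations = x$stage2$evaluation_count)
}

#' Tidy a reciprocity result
#'
#' @param x A `reciprocity_result`.
#' @param ... Unused.
#' @return The per-K restricted-montage table.
#' @export
tidy.reciprocity_result <- function(x, ...) x$per_K

#' @rdname tidy.reciprocity_result
#' @export
glance.reciprocity_result <- function(x, ...) {
  lab <- names(x$back_projection)
  tibble(gamma_max = x$bipolar$gamma_max,
         anode = lab[x$bipolar$anode], cathode = lab[x$bipolar$cathode],
         mu = x$mu, gamma_cap = x$gamma, degenerate = x$bipolar$degenerate)
}

#' Heatmap of a lattice search
#'
#' Intensity (or focality) over the `(alpha, epsilon)` dB plane, with the
#' maximizers marked.
#'
#' @param object A `lattice_result`.
#' @param metric `"gamma"` or `"theta"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lattice_result <- function(object, metric = c("gamma", "theta"),
                                    ...) {
  metric <- match.arg(metric)
  col <- if (metric == "gamma") "gamma_metric" else "theta_metric"
  df <- object$trace[object$trace$status == "optimal", ]
  df$value <- df[[col]]
  df <- df[is.finite(df$value), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$alpha_db, .data$epsilon_db)) +
    ggplot2::labs(x = expression(alpha ~ "(dB)"),
                  y = expression(epsilon ~ "(dB)"),
                  fill = if (metric == "gamma") {
                    expression(Gamma ~ (A / m^2))
                  } else expression(Theta)) +
    ggplot2::theme_minimal()
  p <- if (object$method %in% c("exhaustive")) {
    p + ggplot2::geom_tile(ggplot2::aes(fill = .data$value)) +
      ggplot2::scale_fill_viridis_c()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$value), size = 2) +
      ggplot2::scale_colour_viridis_c(
        name = if (metric == "gamma") expression(Gamma) else expression(Theta))
  }
  mk <- if (metric == "gamma") object$gamma_maximizer else object$theta_maximizer
  if (!is.null(mk)) {
    p <- p + ggplot2::annotate("point", x = mk$alpha_db, y = mk$epsilon_db,
                               shape = 8, size = 4, colour = "red")
  }
  p
}

#' Stem plot of a montage
#'
#' Electrode currents of the final two-stage montage.
#'
#' @param object A `stage_outcome`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stage_outcome <- function(object, ...) {
  df <- object$montage[object$montage$active, ]
  df$label <- factor(df$label, levels = df$label[order(df$current_mA)])
  ggplot2::ggplot(df, ggplot2::aes(.data$label, .data$current_mA)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$label, yend = 0)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$current_mA > 0),
                        size = 3, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "current (mA)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
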