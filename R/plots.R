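#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a gap-spectrum with its smooth fit and derivative
#' @param object A `gap_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gap_spectrum <- function(object, ...) {
  df <- tidy(object)
  long <- tidyr::pivot_longer(df, c("eigenvalue", "fitted", "gap_curve",
                                    "gap_derivative"),
                              names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$harmonic, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "harmonic index", y = NULL,
                  title = "Eigenvalue gap-spectrum") +
    ggplot2::theme_minimal()
}

#' Plot an inter-subject agreement profile
#' @param object An `agreement_profile`.
#' @param ... Unused.
#' @return A ggplot with the median and 5-95 percentile band per harmonic.
#' @export
autoplot.agreement_profile <- function(object, ...) {
  df <- object$summary
  ggplot2::ggplot(df, ggplot2::aes(x = .data$harmonic)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p05, ymax = .data$p95),
                         alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median)) +
    ggplot2::labs(x = "consensus harmonic index", y = "|cosine similarity|",
                  title = sprintf("Inter-subject agreement (%s)",
                                  if (object$matched) "matched" else "unmatched")) +
    ggplot2::theme_minimal()
}

#' Plot per-harmonic stability slopes
#' @param object A `stability_result`.
#' @param partition Optional `regime_partition` to color by regime.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stability_result <- function(object, partition = NULL, ...) {
  df <- tidy(object)
  if (!is.null(partition)) df$regime <- partition$labels
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$harmonic, y = .data$stability))
  p <- if (is.null(partition)) p + ggplot2::geom_point() else
    p + ggplot2::geom_point(ggplot2::aes(color = .data$regime))
  p + ggplot2::labs(x = "harmonic index",
                    y = "stability (d ln P / d sigma)",
                    title = "Harmonic stability under Rayleigh perturbation") +
    ggplot2::theme_minimal()
}

#' Plot regime vote fractions
#' @param object A `regime_partition`.
#' @param ... Unused.
#' @return A ggplot of per-harmonic vote fractions with regime bounds.
#' @export
autoplot.regime_partition <- function(object, ...) {
  long <- tidyr::pivot_longer(object$votes,
                              c("integrative", "degenerate", "segregative"),
                              names_to = "regime", values_to = "vote")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$harmonic, y = .data$vote,
                                     color = .data$regime)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$bounds, linetype = "dashed") +
    ggplot2::labs(x = "consensus harmonic index", y = "vote fraction",
                  title = "Regime votes and consensus bounds") +
    ggplot2::theme_minimal()
}

#' Ternary plot of regime dynamics
#'
#' Projects simplex coordinates onto the plane (equilateral-triangle
#' barycentric mapping) and draws the per-timepoint trajectory with the
#' time-averaged point.
#'
#' @param object A `ternary_dynamics`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ternary_dynamics <- function(object, ...) {
  f <- object$fractions
  to_xy <- function(f3) {
    cbind(x = f3[, 2] + f3[, 3] / 2, y = f3[, 3] * sqrt(3) / 2)
  }
  xy <- tibble::as_tibble(to_xy(f))
  mxy <- to_xy(matrix(object$mean_fractions, nrow = 1))
  tri <- tibble::tibble(x = c(0, 1, 0.5, 0), y = c(0, 0, sqrt(3) / 2, 0))
  ggplot2::ggplot(xy, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = tri, color = "grey40") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::annotate("point", x = mxy[1], y = mxy[2], color = "red", size = 3) +
    ggplot2::annotate("text", x = c(-0.03, 1.03, 0.5), y = c(-0.03, -0.03, sqrt(3) / 2 + 0.05),
                      label = c("integrative", "degenerate", "segregative"),
                      size = 3) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = "Ternary regime dynamics")
}

#' @importFrom rlang .data
NULL
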