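#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a position-residue enrichment profile
#'
#' Heat-map rendering of the standardized log-ratio profile: residues
#' enriched over the background composition in red, depleted in blue.
#' Absent residues (log-ratio of minus infinity) are floored at a display
#' minimum, mirroring how logos draw them "not to scale".
#'
#' @param object A \code{frequency_profile}.
#' @param floor Display floor for minus-infinity cells (default -1.5).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.frequency_profile <- function(object, floor = -1.5, ...) {
  df <- tibble::as_tibble(object)
  df$log_ratio_display <- pmax(df$log_ratio, floor)
  df$position <- factor(df$position, levels = unique(df$position))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$residue,
                                   fill = .data$log_ratio_display)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0,
                                  name = "log10 ratio") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Residue enrichment by window position") +
    ggplot2::theme_minimal()
}

#' Plot a protein scan track
#'
#' Cleavage probability after each residue, with called sites highlighted.
#'
#' @param object A \code{scan_track} from [scan_protein()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scan_track <- function(object, ...) {
  df <- tibble::as_tibble(object)
  th <- attr(object, "threshold")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bond_after,
                                   y = .data$probability)) +
    ggplot2::geom_line(na.rm = TRUE, colour = "grey40") +
    ggplot2::geom_point(data = df[which(df$called), ], colour = "red",
                        na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = th, linetype = "dashed") +
    ggplot2::labs(x = "bond after residue", y = "cleavage probability",
                  title = attr(object, "id")) +
    ggplot2::theme_minimal()
}

#' Plot classification performance against threshold
#'
#' Sensitivity, specificity, predictive values and accuracy as functions of
#' the classification threshold.
#'
#' @param object A \code{performance_curve}.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.performance_curve <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("sensitivity", "specificity", "ppv", "npv",
                          "accuracy"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "classification threshold", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot predicted against measured catalytic efficiency
#'
#' Scatter of model predictions against measurements with the least-squares
#' calibration line, annotated with r.
#'
#' @param object A \code{pls_qsar} model (training data are stored on the
#'   object).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pls_qsar <- function(object, ...) {
  df <- tibble::tibble(measured = object$response,
                       predicted = object$fitted)
  ev <- evaluate_regression(df$predicted, df$measured)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$measured,
                                   y = .data$predicted)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = ev$slope, intercept = ev$intercept,
                         colour = "firebrick") +
    ggplot2::labs(
      x = expression(measured ~ k[cat] / K[m] ~ (M^-1 * s^-1)),
      y = expression(predicted ~ k[cat] / K[m] ~ (M^-1 * s^-1)),
      subtitle = sprintf("r = %.3f, y = %.3f x + %.1f", ev$r, ev$slope,
                         ev$intercept)
    ) +
    ggplot2::theme_minimal()
}

#' Double-reciprocal (Lineweaver-Burk) diagnostic plot
#'
#' @param s0 Initial substrate concentrations (M).
#' @param v0 Initial velocities (M/s).
#' @param fit Optional one-row tibble from [lineweaver_burk()] to draw the
#'   fitted line.
#' @return A ggplot.
#' @export
plot_lineweaver_burk <- function(s0, v0, fit = NULL) {
  ok <- is.finite(v0) & v0 > 0
  df <- tibble::tibble(x = 1 / s0[ok], y = 1 / v0[ok])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(1 / group("[", S, "]")[0] ~ (M^-1)),
                  y = expression(1 / v[0] ~ (M^-1 * s))) +
    ggplot2::theme_minimal()
  if (!is.null(fit) && is.finite(fit$slope)) {
    intercept <- mean(df$y) - fit$slope * mean(df$x)
    p <- p + ggplot2::geom_abline(slope = fit$slope, intercept = intercept,
                                  colour = "firebrick")
  }
  p
}
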