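# ggplot2 views of the result tables.

#' Plot multiplier observations with their smoothing-spline curve
#'
#' Scatter of per-visit growth-remaining multipliers against spurt-relative
#' timing or chronological age, one panel per method, with the GCV smoothing
#' spline overlaid.
#'
#' @param observations A [compute_multipliers()] tibble.
#' @param predictor `"timing"` or `"age"`.
#' @return A ggplot object.
#' @export
plot_multipliers <- function(observations, predictor = c("timing", "age")) {
  predictor <- match.arg(predictor)
  xvar <- if (predictor == "timing") "timing_yr" else "age_yr"
  xlab <- if (predictor == "timing") {
    "Timing relative to PGA90 (yr)"
  } else "Chronological age (yr)"
  ggplot2::ggplot(observations,
                  ggplot2::aes(x = .data[[xvar]], y = .data$multiplier)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_smooth(method = "gam", formula = y ~ s(x),
                         se = FALSE, linewidth = 0.7) +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(x = xlab, y = "Growth-remaining multiplier") +
    ggplot2::theme_minimal()
}

#' Plot a multiplier table on the timing grid
#'
#' Binned multiplier means with +/- 1 sd ribbons per method, optionally with
#' the reference columns overlaid.
#'
#' @param table A [build_multiplier_table()] tibble.
#' @param reference Overlay [multiplier_reference()] columns (default TRUE).
#' @return A ggplot object.
#' @export
plot_multiplier_table <- function(table, reference = TRUE) {
  p <- ggplot2::ggplot(
    dplyr::filter(table, .data$n > 0),
    ggplot2::aes(x = .data$timing_yr, y = .data$multiplier,
                 color = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::labs(x = "Timing relative to PGA90 (yr)",
                  y = "Growth-remaining multiplier", color = "Method") +
    ggplot2::theme_minimal()
  if (reference) {
    ref <- multiplier_reference() |>
      tidyr::pivot_longer(-"timing_yr", names_to = "column",
                          values_to = "multiplier")
    p <- p + ggplot2::geom_line(
      data = ref,
      ggplot2::aes(x = .data$timing_yr, y = .data$multiplier,
                   group = .data$column),
      inherit.aes = FALSE, linetype = "dashed", color = "grey40")
  }
  p
}

#' Autoplot a multiplier spline
#'
#' @method autoplot multiplier_spline
#' @param object A [fit_multiplier_spline()] result.
#' @param ... Unused.
#' @return A ggplot object showing the observations and the fitted curve.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.multiplier_spline <- function(object, ...) {
  pts <- object$points
  grid <- seq(min(pts$predictor_value), max(pts$predictor_value),
              length.out = 200)
  curve <- tibble::tibble(x = grid, y = stats::predict(object$fit, grid)$y)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$predictor_value,
                                    y = .data$multiplier)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_line(data = curve, ggplot2::aes(x = .data$x, y = .data$y),
                       color = "steelblue", linewidth = 0.8) +
    ggplot2::labs(
      x = if (object$predictor == "timing") {
        "Timing relative to PGA90 (yr)"
      } else "Chronological age (yr)",
      y = "Growth-remaining multiplier") +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot
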