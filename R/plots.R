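#' Plot a wavelet power spectrum
#'
#' Heat map of power over time and (log-scaled) period, with the cone of
#' influence drawn as a solid line and, optionally, significance areas
#' outlined.
#'
#' @param object A `wavelet_spectrum`.
#' @param mask Optional `significance_mask` to outline.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot wavelet_spectrum
#' @export
autoplot.wavelet_spectrum <- function(object, mask = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$period)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$power)) +
    ggplot2::geom_line(
      data = cone_of_influence(object),
      ggplot2::aes(x = .data$time, y = .data$max_period),
      linewidth = 0.4
    ) +
    ggplot2::scale_y_continuous(
      trans = "log2",
      limits = range(object$periods), oob = scales_squish
    ) +
    ggplot2::scale_fill_gradient(low = "white", high = "red") +
    ggplot2::labs(
      title = object$label, x = "time (days)", y = "period (days)",
      fill = "power"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(mask)) {
    md <- tidy(mask)
    p <- p + ggplot2::geom_contour(
      data = md,
      ggplot2::aes(z = as.numeric(.data$significant)),
      breaks = 0.5, colour = "black", linetype = "dotted", linewidth = 0.3
    )
  }
  p
}

# minimal squish (avoid a scales dependency for one helper)
scales_squish <- function(x, range = c(0, 1), only.finite = TRUE) {
  force(range)
  finite <- if (only.finite) is.finite(x) else TRUE
  x[finite & x < range[1]] <- range[1]
  x[finite & x > range[2]] <- range[2]
  x
}

#' Plot a Bk curve with its rejection line
#'
#' Bk values against the number of clusters `k` (points) with the one-sided
#' rejection line under the unrelated-trees null (red).
#'
#' @param object A `bk_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bk_curve
#' @export
autoplot.bk_curve <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$rejection), colour = "red") +
    ggplot2::geom_point(ggplot2::aes(y = .data$bk)) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "number of clusters k", y = expression(B[k]),
      subtitle = sprintf(
        "one-sided %.0f%% rejection line (%s null)",
        100 * (1 - attr(object, "alpha")), attr(object, "null_method")
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a series panel as stacked facets
#'
#' @param series Tibble of `label`, `time`, `value`, or a `synth_panel`.
#' @return A ggplot with one facet per series.
#' @export
plot_series_panel <- function(series) {
  df <- as_panel_tibble(series)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$label)) +
    ggplot2::labs(x = "time (days)", y = NULL) +
    ggplot2::theme_minimal()
}
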