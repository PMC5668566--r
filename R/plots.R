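#' Plot a polysome profile, optionally with its segmentation
#'
#' The A254 trace against gradient position, with fraction boundaries as
#' ticks and, when a segmentation is supplied, shaded sedimentation regions.
#'
#' @param object A `polysome_profile`.
#' @param segmentation Optional `peak_segmentation`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.polysome_profile <- function(object, segmentation = NULL, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$absorbance))
  if (!is.null(segmentation)) {
    seg <- as_tibble(segmentation)
    seg <- seg[seg$end > seg$start, ]
    p <- p + ggplot2::geom_rect(
      data = seg,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf, fill = .data$region),
      alpha = 0.15, inherit.aes = FALSE)
  }
  p + ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "gradient position (light → heavy)",
                  y = "A254 (AU)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Volcano-style plot of a differential-TE result
#'
#' log2 delta-TE against -log10 p, significant genes highlighted.
#'
#' @param object A `te_result` from [test_delta_te()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.te_result <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2dte,
                                   y = -log10(.data$p_value),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 ΔTE (case - control)", y = "-log10 p",
                  colour = "p < 0.05") +
    ggplot2::theme_minimal()
}

#' Bar plot of co-sedimentation signal shares across fractions
#'
#' @param shares Normalised table from [normalize_distribution()].
#' @return A ggplot, faceted by protein.
#' @export
plot_cosed <- function(shares) {
  check_columns(shares, c("protein", "fraction_index", "share"), "shares")
  ggplot2::ggplot(shares, ggplot2::aes(x = factor(.data$fraction_index),
                                       y = .data$share)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_grid(protein ~ sample) +
    ggplot2::labs(x = "fraction (light → heavy)", y = "signal share") +
    ggplot2::theme_minimal()
}
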