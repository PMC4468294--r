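#' Plot an analyzed trace
#'
#' Draws the measured profile, the estimated unresorbed-surface baseline,
#' and the detected pit extents shaded by shape class.
#'
#' @param object A `pit_analysis` from [analyze_trace].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pit_analysis
#' @export
autoplot.pit_analysis <- function(object, ...) {
  tr <- tibble::tibble(position = object$trace$position,
                       height = object$trace$height,
                       level = object$baseline$level)
  p <- ggplot2::ggplot(tr, ggplot2::aes(x = .data$position)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$height),
                       linewidth = 0.25, colour = "grey30")
  if (nrow(object$pits) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = object$pits,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   fill = .data$shape_class),
      ymin = -Inf, ymax = Inf, alpha = 0.25, inherit.aes = FALSE
    )
  }
  p +
    ggplot2::geom_line(ggplot2::aes(y = .data$level),
                       linetype = "dashed", colour = "firebrick") +
    ggplot2::scale_fill_brewer(palette = "Set2", drop = FALSE) +
    ggplot2::labs(
      x = "position (µm)", y = "height (µm)",
      fill = "pit shape",
      title = sprintf("%s: %d pits", object$source_id, nrow(object$pits))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a comparison table
#'
#' P-values per endpoint and contrast, with the significance level marked.
#'
#' @param object A `pit_comparison` from [compare_groups].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pit_comparison
#' @export
autoplot.pit_comparison <- function(object, ...) {
  alpha <- attr(object, "alpha")
  df <- tibble::as_tibble(object) |>
    dplyr::filter(.data$flag == "")
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p_value),
                                   y = .data$endpoint,
                                   colour = .data$significant,
                                   shape = .data$test)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = -log10(alpha), linetype = "dotted") +
    ggplot2::facet_wrap(ggplot2::vars(.data$scope, .data$comparison)) +
    ggplot2::labs(x = expression(-log[10](p)), y = NULL,
                  colour = sprintf("p < %g", alpha), shape = "test") +
    ggplot2::theme_minimal()
}

#' Plot a planar resorption mask
#'
#' @param object A [planar_mask].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot planar_mask
#' @export
autoplot.planar_mask <- function(object, ...) {
  g <- expand.grid(x = seq_len(nrow(object)), y = seq_len(ncol(object)))
  g$resorbed <- as.vector(unclass(object))
  ggplot2::ggplot(g, ggplot2::aes(.data$x, .data$y,
                                  fill = .data$resorbed)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c("FALSE" = "grey90",
                                          "TRUE" = "grey20")) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("resorbed area: %.1f%%", resorbed_area_percent(object)),
      x = NULL, y = NULL, fill = "resorbed"
    ) +
    ggplot2::theme_void()
}

#' Plot the cross-subject pit-shape distribution
#'
#' Bars are cross-subject medians of the subject-level shape percentages;
#' whiskers span the 25th-75th percentiles.
#'
#' @param summaries A subject-summary tibble ([summarize_cohort]) or a
#'   [shape_distribution] result.
#' @return A ggplot.
#' @export
plot_shape_distribution <- function(summaries) {
  dist <- if ("median_pct" %in% names(summaries)) {
    summaries
  } else {
    shape_distribution(summaries)
  }
  ggplot2::ggplot(dist, ggplot2::aes(x = .data$shape_class,
                                     y = .data$median_pct,
                                     fill = .data$condition)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$q1_pct, ymax = .data$q3_pct),
      position = ggplot2::position_dodge(0.8), width = 0.25
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$group)) +
    ggplot2::labs(x = NULL, y = "pits (%)", fill = "condition") +
    ggplot2::theme_minimal()
}
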