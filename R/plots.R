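#' Plot the neighborhood enrichment cluster map
#'
#' Heatmap of the scaled enrichment score (cell types x final neighborhoods)
#' — the "cluster map" used to read off each neighborhood's identity.
#'
#' @param object A `cn_model` from [detect_neighborhoods()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cn_model
#' @export
autoplot.cn_model <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(
      x = .data$cn_final,
      y = factor(.data$cell_type, levels = rev(cell_type_vocabulary())),
      fill = .data$enrichment
    )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0) +
    ggplot2::labs(x = "Cellular neighborhood", y = NULL,
                  fill = "Scaled\nenrichment") +
    ggplot2::theme_minimal()
}

#' Plot a spot's Voronoi diagram colored by a label
#'
#' @param polygons Output of [voronoi_cells()].
#' @param fill Column to color polygons by (default `cn_final`; use
#'   `cell_type` for a phenotype map).
#' @return A ggplot object (one facet per spot).
#' @export
plot_voronoi <- function(polygons, fill = "cn_final") {
  if (!fill %in% names(polygons)) {
    abort(sprintf("column '%s' not present in the polygon table.", fill))
  }
  ggplot2::ggplot(polygons, ggplot2::aes(
    x = .data$vx, y = .data$vy, group = .data$cell_id,
    fill = .data[[fill]]
  )) +
    ggplot2::geom_polygon(color = "grey30", linewidth = 0.05) +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~spot_id) +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", fill = fill) +
    ggplot2::theme_void()
}

#' Kaplan-Meier curves for dichotomized patient groups
#'
#' @param records Survival records (`time_months`, `event`) with a `group`
#'   column (e.g. from [dichotomize()]).
#' @return A ggplot object of step survival curves; the log-rank p-value is
#'   shown in the subtitle.
#' @export
plot_km <- function(records) {
  km <- km_estimate(records)
  has_group <- "group" %in% names(km)
  p <- if (has_group) {
    lr <- logrank_test(records)
    ggplot2::ggplot(km, ggplot2::aes(.data$time, .data$survival,
                                     color = .data$group)) +
      ggplot2::labs(subtitle = sprintf("log-rank p = %.3g", lr$p_value))
  } else {
    ggplot2::ggplot(km, ggplot2::aes(.data$time, .data$survival))
  }
  p +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Overall survival",
                  color = NULL) +
    ggplot2::theme_classic()
}
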