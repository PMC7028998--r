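# ggplot2 views of the main result types. Maps are drawn as points at cell
# centroids (cells are near-equal-area, so point maps are faithful); use
# grid_to_geojson() for polygon rendering in GIS tools.

#' Map a diversity pattern
#'
#' @param object A `pattern_set`.
#' @param grid The `hex_grid` the pattern lives on (for centroids).
#' @param pattern Column to map.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pattern_set <- function(object, grid,
                                 pattern = "breeding_migrants", ...) {
  d <- dplyr::left_join(object,
                        tibble(cell_id = grid$cell_id, lon = grid$lon,
                               lat = grid$lat), by = "cell_id")
  ggplot2::ggplot(d, ggplot2::aes(.data$lon, .data$lat,
                                  colour = .data[[pattern]])) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_viridis_c(name = pattern) +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a parameter scan
#'
#' Species richness, proportion of migrants and (when scored) the
#' composite pattern correlation against the scanned parameter value.
#'
#' @param object A `scan_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scan_result <- function(object, ...) {
  d <- object %>%
    select("value", "n_species", "prop_migrants", "composite") %>%
    tidyr::pivot_longer(-"value", names_to = "metric",
                        values_to = "metric_value")
  d <- d[!is.na(d$metric_value), ]
  ggplot2::ggplot(d, ggplot2::aes(.data$value, .data$metric_value)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = object$parameter[1], y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot migration time series across slices
#'
#' @param timeseries The `timeseries` tibble from [simulate_timeseries()].
#' @param metric Column to plot (e.g. `"prop_migrants"`,
#'   `"rel_mean_d_m"`).
#' @return A ggplot.
#' @export
plot_timeseries <- function(timeseries, metric = "prop_migrants") {
  d <- timeseries %>%
    mutate(slice_num = suppressWarnings(as.numeric(.data$slice)))
  ggplot2::ggplot(d, ggplot2::aes(.data$slice_num, .data[[metric]],
                                  colour = .data$region)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "years before present", y = metric) +
    ggplot2::theme_minimal()
}
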