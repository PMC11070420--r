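#' Histogram of deficit-area sizes on a log scale
#'
#' Displays the distribution whose summary features feed the classifier:
#' per-region areas of a deficit (or intercapillary) region set, plotted on
#' a log10 axis. The log scale is display only; features are computed on
#' raw pixel areas.
#'
#' @param regions A `region_set`.
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_area_histogram <- function(regions, bins = 30) {
  d <- tidy(regions)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$area_px)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey30") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "region area (pixels, log scale)", y = "count") +
    ggplot2::theme_minimal()
}

#' Display a perfusion-distance map
#'
#' @param pd_map A [perfusion_distance_map()].
#' @return A ggplot raster of distances in pixels.
#' @export
plot_distance_map <- function(pd_map) {
  d <- tibble::tibble(
    row = rep(seq_len(nrow(pd_map)), times = ncol(pd_map)),
    col = rep(seq_len(ncol(pd_map)), each = nrow(pd_map)),
    distance = as.numeric(pd_map)
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$col, .data$row,
                                  fill = .data$distance)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "distance (px)") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
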