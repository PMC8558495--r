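#' Choropleth of a per-catchment map
#'
#' @param object an `aqrisk_map` (from [predict_window()]) or any tibble
#'   with `huc_id` and a value column.
#' @param catch the [catchments()] tibble supplying polygon outlines.
#' @param fill name of the column to shade by (defaults to the map's
#'   ensemble value column).
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.aqrisk_map <- function(object, catch, fill = NULL, ...) {
  fill <- fill %||% intersect(c("prob", "pred"), names(object))[1]
  poly <- purrr::map2_dfr(catch$huc_id, catch$geometry, function(id, g) {
    tibble::tibble(huc_id = id, lon = g[, 1], lat = g[, 2])
  })
  poly <- dplyr::left_join(
    poly, object[, c("huc_id", fill)], by = "huc_id"
  )
  ggplot2::ggplot(
    poly,
    ggplot2::aes(.data$lon, .data$lat, group = .data$huc_id, fill = .data[[fill]])
  ) +
    ggplot2::geom_polygon(colour = "grey20", linewidth = 0.1) +
    ggplot2::scale_fill_viridis_c(name = fill) +
    ggplot2::coord_quickmap() +
    ggplot2::labs(
      x = "Longitude", y = "Latitude",
      title = attr(object, "window") %||% NULL
    ) +
    ggplot2::theme_minimal()
}

#' Partial-dependence curve plot
#'
#' @param object an `aqrisk_pdp` from [pdp()].
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.aqrisk_pdp <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$grid, .data$response)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = object$covariate[1], y = "Mean predicted response"
    ) +
    ggplot2::theme_minimal()
}

#' Importance-tally bar chart
#'
#' @param object an `aqrisk_importance` from [importance_ensemble()].
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.aqrisk_importance <- function(object, ...) {
  tl <- dplyr::mutate(
    object$tally,
    covariate = stats::reorder(.data$covariate, .data$count)
  )
  ggplot2::ggplot(tl, ggplot2::aes(.data$count, .data$covariate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "Appearances in a top-3 importance list", y = NULL
    ) +
    ggplot2::theme_minimal()
}
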