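## ggplot2 autoplot methods for the package's result types.

raster_df <- function(m, pixel) {
  tibble(
    x = rep((seq_len(ncol(m)) - 0.5) * pixel, each = nrow(m)),
    y = rep((seq_len(nrow(m)) - 0.5) * pixel, times = ncol(m)),
    value = as.vector(m)
  )
}

#' Plot an activity map or count image
#'
#' Renders the image as a physical-coordinate raster (mm), superior edge up.
#'
#' @param object A `mibg_activity_map` or `mibg_count_image`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mibg_activity_map <- function(object, ...) {
  df <- raster_df(unclass(object), attr(object, "pixel_size_mm"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(name = "relative\nactivity") +
    ggplot2::labs(
      title = sprintf("Digital phantom, %s view", attr(object, "view")),
      x = "mm", y = "mm"
    )
}

#' @rdname autoplot.mibg_activity_map
#' @export
autoplot.mibg_count_image <- function(object, ...) {
  df <- raster_df(unclass(object), attr(object, "pixel_size_mm"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(name = "counts") +
    ggplot2::labs(x = "mm", y = "mm")
}

#' Heat maps of HMR over the collimator design grid
#'
#' One tile per (hole diameter, septal thickness), faceted by collimator
#' length -- the standard way to display the design dependence of the
#' simulated HMR.
#'
#' @param object A `mibg_sweep` from [sweep_collimator_designs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mibg_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = factor(.data$hole_diameter_mm),
    y = factor(.data$septal_thickness_mm),
    fill = .data$hmr
  )) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~length_mm, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(name = "HMR") +
    ggplot2::labs(x = "hole diameter (mm)", y = "septal thickness (mm)")
}

#' Group conversion coefficients with error bars
#'
#' @param object A `mibg_cc_table` from [aggregate_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mibg_cc_table <- function(object, ...) {
  df <- object |>
    dplyr::group_by(.data$collimator_group) |>
    dplyr::summarise(
      mean_cc = sum(.data$mean_cc * .data$n) / sum(.data$n),
      sd_cc = sqrt(sum(.data$sd_cc^2 * (.data$n - 1), na.rm = TRUE) /
        max(sum(.data$n) - dplyr::n(), 1)),
      n = sum(.data$n), .groups = "drop"
    ) |>
    dplyr::mutate(collimator_group = factor(.data$collimator_group,
      levels = COLLIMATOR_GROUPS
    ))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$collimator_group, y = .data$mean_cc)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean_cc - .data$sd_cc,
        ymax = .data$mean_cc + .data$sd_cc
      ),
      width = 0.25
    ) +
    ggplot2::labs(x = "collimator group", y = "conversion coefficient")
}
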