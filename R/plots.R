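#' Plot an hour-by-day behavioral state matrix
#'
#' Tile plot of the modal state per (day, hour) cell of one calendar month;
#' empty cells are blank.
#'
#' @param object A `tm_state_matrix` ([state_matrix()]).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.tm_state_matrix <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$day, y = .data$hour,
                               fill = .data$state)) +
    ggplot2::geom_tile(color = "grey90", linewidth = 0.2) +
    ggplot2::scale_fill_manual(
      values = c(rest = "#4575b4", forage = "#d73027", transit = "#fee090"),
      na.value = "white", drop = FALSE) +
    ggplot2::scale_y_continuous(breaks = seq(0, 22, 4)) +
    ggplot2::labs(
      title = sprintf("%s — %04d-%02d", attr(object, "animal_id"),
                      attr(object, "year"), attr(object, "month")),
      x = "day of month", y = "hour of day", fill = "state") +
    ggplot2::theme_minimal()
}

#' Plot mined association rules
#'
#' Support versus lift, point size by co-occurrence count, color by phi
#' correlation band.
#'
#' @param object A `tm_rules` tibble ([mine_rules()]).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.tm_rules <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(rule = paste(.data$antecedent, "→", .data$consequent))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sup, y = .data$lift,
                                   size = .data$count,
                                   color = .data$phi_band)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, color = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "support", y = "lift", color = "phi band",
                  size = "co-occurrences") +
    ggplot2::theme_minimal()
}

#' Plot a kernel utilization distribution
#'
#' Density raster with the 50% (core) and 95% (home range) isopleth
#' boundaries drawn as contours.
#'
#' @param object A `tm_ud` ([kernel_ud()]).
#' @param isopleths Isopleth levels to outline.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.tm_ud <- function(object, isopleths = c(0.5, 0.95), ...) {
  df <- tidy(object)
  breaks <- purrr::map_dbl(isopleths, function(p) {
    iso <- isopleth(object, p)
    min(object$z[iso$mask])
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x / 1000, y = .data$y / 1000)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$density)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$density),
                          breaks = sort(breaks), color = "white",
                          linewidth = 0.4) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "east (km)", y = "north (km)", fill = "UD density") +
    ggplot2::theme_minimal()
}
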