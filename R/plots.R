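#' Plot the spatial profile of a driver
#'
#' Monthly driving-area hulls (grey polygons), monthly mean centers (open
#' squares) and primary locations (red stars) in the projected plane — the
#' standard one-panel spatial-profile view.
#'
#' @param profiles A `drivecrumb_profile`.
#' @param vehicle Vehicle id to plot (default: first).
#' @return A ggplot object.
#' @export
plot_spatial_profile <- function(profiles, vehicle = NULL) {
  vehicle <- vehicle %||% profiles$vehicle_id[1]
  p <- filter(as_tibble(profiles), .data$vehicle_id == vehicle)
  hull_df <- purrr::map_dfr(which(!purrr::map_lgl(p$driving_area_hull, is.null)),
                            function(i) {
    h <- p$driving_area_hull[[i]]
    tibble(local_month = p$local_month[i], x = h[, 1] / 1000, y = h[, 2] / 1000)
  })
  prim <- attr(profiles, "primary_locations")
  gg <- ggplot2::ggplot() +
    ggplot2::geom_polygon(
      data = hull_df,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$local_month),
      fill = "grey70", colour = "grey40", alpha = 0.3
    ) +
    ggplot2::geom_point(
      data = filter(p, !is.na(.data$mean_center_x)),
      ggplot2::aes(x = .data$mean_center_x / 1000, y = .data$mean_center_y / 1000),
      shape = 0, size = 2.5
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "east (km)", y = "north (km)",
                  title = paste("Spatial profile:", vehicle))
  if (!is.null(prim) && nrow(prim) > 0) {
    gg <- gg + ggplot2::geom_point(
      data = filter(prim, .data$vehicle_id == vehicle),
      ggplot2::aes(x = .data$centroid_x / 1000, y = .data$centroid_y / 1000),
      shape = 8, colour = "red", size = 3
    )
  }
  gg
}

#' Plot monthly trips by light phase
#'
#' @param profiles A `drivecrumb_profile`.
#' @return A ggplot object (stacked bars per driver-month).
#' @export
plot_trips_by_light <- function(profiles) {
  long <- as_tibble(profiles) %>%
    select("vehicle_id", "local_month", day = "n_trips_day",
           dawn = "n_trips_dawn", dusk = "n_trips_dusk",
           night = "n_trips_night") %>%
    tidyr::pivot_longer(c("day", "dawn", "dusk", "night"),
                        names_to = "phase", values_to = "n") %>%
    mutate(phase = factor(.data$phase, c("day", "dawn", "dusk", "night")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$local_month, y = .data$n,
                                     fill = .data$phase)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~vehicle_id) +
    ggplot2::labs(x = NULL, y = "trips", fill = "phase") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot unique-destination counts by radius
#'
#' @param profiles A `drivecrumb_profile`.
#' @return A ggplot object.
#' @export
plot_destinations <- function(profiles) {
  long <- as_tibble(profiles) %>%
    select("vehicle_id", "local_month", dplyr::starts_with("n_destinations_")) %>%
    tidyr::pivot_longer(dplyr::starts_with("n_destinations_"),
                        names_to = "radius", values_to = "n") %>%
    mutate(radius = sub("n_destinations_", "", .data$radius))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$local_month, y = .data$n,
                                     colour = .data$radius, group = .data$radius)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~vehicle_id) +
    ggplot2::labs(x = NULL, y = "unique destinations", colour = "radius")
}

#' @export
autoplot.drivecrumb_profile <- function(object, type = c("light", "spatial",
                                                         "destinations"), ...) {
  type <- match.arg(type)
  switch(type,
    light = plot_trips_by_light(object),
    spatial = plot_spatial_profile(object, ...),
    destinations = plot_destinations(object)
  )
}

#' @export
autoplot.drivecrumb_scenario <- function(object, ...) {
  segs <- purrr::map_dfr(seq_len(nrow(object$segments)), function(i) {
    pl <- object$segments$polyline[[i]]
    tibble(seg = i, x = pl[, 1] / 1000, y = pl[, 2] / 1000,
           mph = object$segments$avg_speed[i])
  })
  crumbs <- project_local(object$crumbs, center = object$config$center)
  ggplot2::ggplot() +
    ggplot2::geom_line(data = segs,
                       ggplot2::aes(x = .data$x, y = .data$y, group = .data$seg,
                                    linewidth = .data$mph),
                       colour = "grey75") +
    ggplot2::scale_linewidth(range = c(0.2, 1)) +
    ggplot2::geom_point(data = crumbs,
                        ggplot2::aes(x = .data$x / 1000, y = .data$y / 1000),
                        size = 0.3, alpha = 0.3) +
    ggplot2::geom_point(data = object$manifest$anchors,
                        ggplot2::aes(x = .data$x / 1000, y = .data$y / 1000),
                        shape = 8, colour = "red", size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "east (km)", y = "north (km)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
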