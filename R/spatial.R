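#' Cluster ignition-on fixes by aggregation distance
#'
#' Clusters are the connected components of the graph joining ignition-on
#' fixes within `link_distance_m` (default 20 ft, the aggregation distance
#' that visually separates parking clusters at consumer-GPS noise levels).
#' Components with fewer than `min_size` points (default 3) are discarded.
#' Each kept cluster carries its convex hull, buffered to a small square when
#' the members are degenerate (fewer than 3 distinct points, or collinear).
#'
#' @param points Tibble with planar `x`, `y` columns in metres (see
#'   [project_local()]); typically the ignition-on crumbs of one driver.
#' @param link_distance_m Link distance in metres (default `20 * 0.3048`).
#' @param min_size Minimum component size to keep (default 3).
#' @return List of class `ignition_clusters`: `points` (input plus
#'   `cluster_id`, `NA` for points in no kept cluster) and `clusters`
#'   (tibble: `cluster_id`, `n`, `centroid_x`, `centroid_y`, list-column
#'   `hull`). Zero ignition-on points yield an empty result with a warning.
#' @export
cluster_ignition_points <- function(points, link_distance_m = 20 * M_PER_FT,
                                    min_size = 3) {
  if (nrow(points) == 0) {
    warn("no ignition-on points to cluster")
    return(structure(list(
      points = mutate(points, cluster_id = integer(0)),
      clusters = tibble(cluster_id = integer(), n = integer(),
                        centroid_x = double(), centroid_y = double(), hull = list())
    ), class = "ignition_clusters"))
  }
  comp <- threshold_components(points$x, points$y, link_distance_m, strict = FALSE)
  sizes <- tabulate(comp)
  keep <- which(sizes >= min_size)
  relabel <- match(comp, keep)        # NA for discarded components
  points$cluster_id <- relabel
  clusters <- purrr::map_dfr(seq_along(keep), function(k) {
    sel <- which(relabel == k)
    hx <- points$x[sel]; hy <- points$y[sel]
    tibble(
      cluster_id = k, n = length(sel),
      centroid_x = mean(hx), centroid_y = mean(hy),
      hull = list(cluster_hull(hx, hy))
    )
  })
  if (nrow(clusters) == 0) {
    clusters <- tibble(cluster_id = integer(), n = integer(),
                       centroid_x = double(), centroid_y = double(), hull = list())
  }
  structure(list(points = points, clusters = clusters), class = "ignition_clusters")
}

# hull of member points; degenerate members get a nominal 1 m square buffer
cluster_hull <- function(x, y) {
  pts <- unique(cbind(x, y))
  if (nrow(pts) >= 3) {
    h <- convex_hull_ring(pts[, 1], pts[, 2])
    if (ring_area(h) > 1e-9) return(h)
  }
  cx <- mean(x); cy <- mean(y)
  r <- max(sqrt((x - cx)^2 + (y - cy)^2), 0) + 1
  cbind(cx + c(-r, r, r, -r), cy + c(-r, -r, r, r))
}

#' Detect primary locations
#'
#' A cluster becomes a primary location when its share of the driver's
#' ignition-on fixes reaches `share_threshold` (default 10%). The centroid is
#' the unweighted mean of member points. Zero, one, or several primaries are
#' possible (a driver with two homes legitimately has two).
#'
#' @param clusters An `ignition_clusters` object, or its `clusters` tibble.
#' @param total_ignition_on Denominator: the driver's total ignition-on count
#'   over the full analysis window. Defaults to the clustered point count when
#'   an `ignition_clusters` object is given.
#' @param share_threshold Minimum share (default 0.10).
#' @return Tibble: `cluster_id`, `n`, `share`, `centroid_x`, `centroid_y`,
#'   list-column `hull`, ordered by decreasing share.
#' @export
detect_primary_locations <- function(clusters, total_ignition_on = NULL,
                                     share_threshold = 0.10) {
  if (inherits(clusters, "ignition_clusters")) {
    total_ignition_on <- total_ignition_on %||% nrow(clusters$points)
    clusters <- clusters$clusters
  }
  stopifnot(!is.null(total_ignition_on), total_ignition_on >= 0)
  if (nrow(clusters) == 0 || total_ignition_on == 0) {
    return(mutate(clusters[0, ], share = double()))
  }
  clusters %>%
    mutate(share = .data$n / total_ignition_on) %>%
    filter(.data$share >= share_threshold) %>%
    arrange(desc(.data$share)) %>%
    select("cluster_id", "n", "share", "centroid_x", "centroid_y", "hull")
}

#' Compute driving areas (convex hulls) per driver-period
#'
#' The driving area is the smallest convex polygon containing all of a
#' driver's breadcrumbs in a period (local-calendar month by default). Periods
#' with fewer than 3 distinct non-collinear points are degenerate: they get
#' zero area and are excluded from overlap metrics.
#'
#' @param crumbs Tibble with `x`, `y` (metres), a driver column and a period
#'   column.
#' @param driver_col,period_col Column names (defaults `vehicle_id`,
#'   `local_month`).
#' @return Tibble: driver, period, `n_crumbs`, `area_km2`, `degenerate`,
#'   list-column `hull` (ring matrix in metres, `NULL` when degenerate).
#' @export
compute_driving_area <- function(crumbs, driver_col = "vehicle_id",
                                 period_col = "local_month") {
  crumbs %>%
    filter(!is.na(.data[[period_col]])) %>%
    group_by(across(all_of(c(driver_col, period_col)))) %>%
    summarise(
      n_crumbs = n(),
      hull = list(period_hull(.data$x, .data$y)),
      .groups = "drop"
    ) %>%
    mutate(
      area_km2 = purrr::map_dbl(.data$hull, ring_area) / 1e6,
      degenerate = purrr::map_lgl(.data$hull, is.null)
    )
}

period_hull <- function(x, y) {
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3) return(NULL)
  h <- convex_hull_ring(pts[, 1], pts[, 2])
  if (nrow(h) < 3 || ring_area(h) < 1e-9) return(NULL)
  h
}

#' Compute mean centers per driver-period
#'
#' The unweighted arithmetic mean of crumb positions in the projected plane,
#' re-expressed in latitude/longitude when a projection centre is available.
#' Being a convex combination, the mean center always lies inside (or on) the
#' period's convex hull.
#'
#' @inheritParams compute_driving_area
#' @param proj_center Optional `c(lat0, lon0)`; defaults to the `proj_center`
#'   attribute left by [project_local()].
#' @return Tibble: driver, period, `n_crumbs`, `x`, `y`, and `latitude`,
#'   `longitude` when a centre is known.
#' @export
compute_mean_center <- function(crumbs, driver_col = "vehicle_id",
                                period_col = "local_month", proj_center = NULL) {
  proj_center <- proj_center %||% attr(crumbs, "proj_center")
  out <- crumbs %>%
    filter(!is.na(.data[[period_col]])) %>%
    group_by(across(all_of(c(driver_col, period_col)))) %>%
    summarise(n_crumbs = n(), x = mean(.data$x), y = mean(.data$y),
              .groups = "drop")
  if (!is.null(proj_center)) {
    ll <- unproject_local(out$x, out$y, proj_center)
    out$latitude <- ll$latitude
    out$longitude <- ll$longitude
  }
  out
}

#' Month-over-month driving-area overlap metrics
#'
#' For each driver: the intersection area of consecutive-month hulls, the area
#' common to all months (intersection of all hulls), the total area (union of
#' all hulls) and their ratio. Degenerate months are skipped with a warning.
#' The "total" denominator is the union area; set `total = "sum"` for the sum
#' of monthly areas instead.
#'
#' @param areas Tibble from [compute_driving_area()].
#' @param driver_col,period_col Column names.
#' @param total Either `"union"` (default) or `"sum"`.
#' @return List of class `overlap_metrics`: `pairwise` (driver, `period_a`,
#'   `period_b`, `overlap_km2`) and `overall` (driver, `n_periods`,
#'   `common_all_km2`, `total_km2`, `ratio`).
#' @export
overlap_metrics <- function(areas, driver_col = "vehicle_id",
                            period_col = "local_month",
                            total = c("union", "sum")) {
  total <- match.arg(total)
  if (any(areas$degenerate)) {
    warn(sprintf("%d degenerate period(s) skipped in overlap metrics",
                 sum(areas$degenerate)))
    areas <- filter(areas, !.data$degenerate)
  }
  split_idx <- split(seq_len(nrow(areas)), areas[[driver_col]])
  pairwise <- purrr::map_dfr(names(split_idx), function(drv) {
    rows <- split_idx[[drv]]
    rows <- rows[order(areas[[period_col]][rows])]
    if (length(rows) < 2) return(NULL)
    purrr::map_dfr(seq_len(length(rows) - 1), function(i) {
      tibble(
        !!driver_col := drv,
        period_a = areas[[period_col]][rows[i]],
        period_b = areas[[period_col]][rows[i + 1]],
        overlap_km2 = intersection_area(areas$hull[[rows[i]]],
                                        areas$hull[[rows[i + 1]]]) / 1e6
      )
    })
  })
  overall <- purrr::map_dfr(names(split_idx), function(drv) {
    rows <- split_idx[[drv]]
    hulls <- areas$hull[rows]
    common <- ring_area(intersect_all_convex(hulls)) / 1e6
    tot <- if (total == "union") union_area_convex(hulls) / 1e6 else sum(areas$area_km2[rows])
    tibble(
      !!driver_col := drv, n_periods = length(rows),
      common_all_km2 = common, total_km2 = tot,
      ratio = if (tot > 0) common / tot else NA_real_
    )
  })
  structure(list(pairwise = pairwise, overall = overall), class = "overlap_metrics")
}

#' Count unique destinations by buffer-dissolve radius
#'
#' A unique destination is one connected component of the union of radius-`r`
#' discs centred at the driver's ignition-on fixes — the classic
#' buffer-then-dissolve count. Two discs merge exactly when their centres are
#' closer than `2r` (strictly: tangent discs touch in one point but are
#' counted separately here; the tie is documented), so the count is computed
#' on the centre graph with [threshold_components()] and verified against an
#' explicit geometric union in the test-suite.
#'
#' @param points Tibble with `x`, `y` in metres (ignition-on fixes of one
#'   driver-period), optionally grouped columns via `group_cols`.
#' @param radii_ft Buffer radii in feet (default `c(100, 250, 500)`).
#' @param group_cols Optional character vector of grouping columns (e.g.
#'   driver and month); counts are computed per group.
#' @return Tibble with the group columns, `radius_ft` and `n_destinations`.
#'   Counts are monotone nonincreasing in radius on the same point set.
#' @export
count_unique_destinations <- function(points, radii_ft = c(100, 250, 500),
                                      group_cols = NULL) {
  stopifnot(all(radii_ft > 0), !is.unsorted(radii_ft, strictly = TRUE))
  count_one <- function(df) {
    purrr::map_dfr(radii_ft, function(r) {
      tibble(
        radius_ft = r,
        n_destinations = if (nrow(df) == 0) 0L else
          max(threshold_components(df$x, df$y, 2 * r * M_PER_FT, strict = TRUE))
      )
    })
  }
  if (is.null(group_cols)) return(count_one(points))
  points %>%
    group_by(across(all_of(group_cols))) %>%
    dplyr::group_modify(~ count_one(.x)) %>%
    ungroup()
}
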