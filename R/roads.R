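#' Build a nearest-segment spatial index
#'
#' Grid-bucket index over street-centerline segments supporting exact
#' nearest-segment queries via ring expansion: the search widens one cell ring
#' at a time and stops only once the best distance found is guaranteed
#' smaller than any segment outside the examined rings, so results always
#' equal an exhaustive scan.
#'
#' @param segments Segment tibble: `segment_id` (unique integer), `name`,
#'   `cfcc`, `avg_speed` (mph, the posted-limit proxy), and list-column
#'   `polyline` of n x 2 matrices in projected metres (>= 2 points each).
#' @param cell_size_m Grid cell size; defaults to a size giving a few
#'   segments per cell.
#' @return Index object (list) for [nearest_segment()].
#' @export
build_segment_index <- function(segments, cell_size_m = NULL) {
  stopifnot(nrow(segments) > 0, !anyDuplicated(segments$segment_id))
  pieces <- purrr::map_dfr(seq_len(nrow(segments)), function(i) {
    pl <- segments$polyline[[i]]
    stopifnot(nrow(pl) >= 2)
    tibble(
      seg_row = i,
      ax = pl[-nrow(pl), 1], ay = pl[-nrow(pl), 2],
      bx = pl[-1, 1], by = pl[-1, 2]
    )
  })
  xr <- range(c(pieces$ax, pieces$bx))
  yr <- range(c(pieces$ay, pieces$by))
  if (is.null(cell_size_m)) {
    span <- max(diff(xr), diff(yr), 1)
    cell_size_m <- max(span / max(ceiling(sqrt(nrow(pieces))), 1), 1)
  }
  cx0 <- floor(pieces$ax / cell_size_m); cx1 <- floor(pieces$bx / cell_size_m)
  cy0 <- floor(pieces$ay / cell_size_m); cy1 <- floor(pieces$by / cell_size_m)
  cells <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(pieces))) {
    for (gx in seq(min(cx0[i], cx1[i]), max(cx0[i], cx1[i]))) {
      for (gy in seq(min(cy0[i], cy1[i]), max(cy0[i], cy1[i]))) {
        key <- paste(gx, gy)
        cells[[key]] <- c(cells[[key]], i)
      }
    }
  }
  list(segments = segments, pieces = pieces, cells = cells,
       cell_size_m = cell_size_m)
}

#' Nearest street segment for query points
#'
#' Exact minimal point-to-polyline distance over all segments; ties (within
#' machine tolerance) break to the lowest `segment_id`, so results are
#' deterministic.
#'
#' @param x,y Query coordinates in the segment frame (metres).
#' @param index From [build_segment_index()].
#' @return Tibble: `near_fid` (nearest `segment_id`), `near_dist` (metres).
#' @export
nearest_segment <- function(x, y, index) {
  stopifnot(length(x) == length(y), length(x) > 0)
  n <- length(x)
  fid <- integer(n)
  dist <- double(n)
  cs <- index$cell_size_m
  max_ring <- max_grid_ring_bound(index)
  bbox <- grid_bbox(index)
  for (q in seq_len(n)) {
    gx <- floor(x[q] / cs); gy <- floor(y[q] / cs)
    far_outside <- gx < bbox[1] - 2 || gx > bbox[2] + 2 ||
      gy < bbox[3] - 2 || gy > bbox[4] + 2
    if (far_outside) {
      # query far off the grid: exhaustive scan (rare; off-network fixes)
      d <- point_seg_dist(x[q], y[q], index$pieces$ax, index$pieces$ay,
                          index$pieces$bx, index$pieces$by)
      dmin <- min(d)
      rows <- index$pieces$seg_row[d <= dmin + 1e-9]
      fid[q] <- min(index$segments$segment_id[rows])
      dist[q] <- dmin
      next
    }
    best <- Inf
    seen <- integer(0)
    ring <- 0
    repeat {
      cand <- integer(0)
      for (dxc in -ring:ring) {
        for (dyc in -ring:ring) {
          if (max(abs(dxc), abs(dyc)) != ring) next
          cand <- c(cand, index$cells[[paste(gx + dxc, gy + dyc)]])
        }
      }
      cand <- unique(cand)
      if (length(cand) > 0) {
        p <- index$pieces[cand, , drop = FALSE]
        d <- point_seg_dist(x[q], y[q], p$ax, p$ay, p$bx, p$by)
        best <- min(best, d)
        seen <- c(seen, cand)
      }
      # clearance: every piece outside rings 0..ring lies in a cell at
      # Chebyshev cell-distance > ring, hence at least ring * cell_size from
      # the query point, so once best <= ring*cs no unseen piece can win
      if ((is.finite(best) && best <= ring * cs) || ring > max_ring) break
      ring <- ring + 1
    }
    p <- index$pieces[unique(seen), , drop = FALSE]
    d <- point_seg_dist(x[q], y[q], p$ax, p$ay, p$bx, p$by)
    dmin <- min(d)
    rows <- p$seg_row[d <= dmin + 1e-9]  # machine-tolerance ties
    fid[q] <- min(index$segments$segment_id[rows])
    dist[q] <- dmin
  }
  tibble(near_fid = fid, near_dist = dist)
}

# upper bound on rings needed from any near-grid start cell
max_grid_ring_bound <- function(index) {
  b <- grid_bbox(index)
  (b[2] - b[1]) + (b[4] - b[3]) + 6
}

grid_bbox <- function(index) {
  keys <- ls(index$cells)
  parts <- do.call(rbind, strsplit(keys, " "))
  gx <- as.numeric(parts[, 1]); gy <- as.numeric(parts[, 2])
  c(min(gx), max(gx), min(gy), max(gy))
}

#' Annotate breadcrumbs with nearest-road attributes
#'
#' Adds the nearest segment id (`near_fid`), distance (`near_dist`, metres),
#' and the inherited attributes `road_name`, `cfcc` and `road_avg_speed` (the
#' posted-limit proxy) to each crumb. Crumbs farther than `max_snap_m` from
#' any segment are flagged `off_network` (their road attributes are `NA`),
#' which avoids nonsense attributes on garage/GPS-glitch fixes.
#'
#' @param crumbs Tibble with projected `x`, `y` columns.
#' @param segments Segment tibble (see [build_segment_index()]).
#' @param max_snap_m Maximum snap distance in metres (default 100).
#' @param index Optional prebuilt index.
#' @return `crumbs` with `near_fid`, `near_dist`, `road_name`, `cfcc`,
#'   `road_avg_speed`, `off_network` columns.
#' @export
annotate_breadcrumbs <- function(crumbs, segments, max_snap_m = 100, index = NULL) {
  if (nrow(crumbs) == 0) {
    return(mutate(crumbs, near_fid = integer(0), near_dist = double(0),
                  road_name = character(0), cfcc = character(0),
                  road_avg_speed = double(0), off_network = logical(0)))
  }
  index <- index %||% build_segment_index(segments)
  nm <- nearest_segment(crumbs$x, crumbs$y, index)
  attrs <- segments %>%
    select("segment_id", road_name = "name", "cfcc", road_avg_speed = "avg_speed")
  out <- crumbs %>%
    mutate(near_fid = nm$near_fid, near_dist = nm$near_dist) %>%
    left_join(attrs, by = c(near_fid = "segment_id")) %>%
    mutate(off_network = .data$near_dist > max_snap_m)
  out$road_name[out$off_network] <- NA_character_
  out$cfcc[out$off_network] <- NA_character_
  out$road_avg_speed[out$off_network] <- NA_real_
  out
}

#' Read and write street segments as GeoJSON LineStrings
#'
#' Segment geometry is exchanged as lon/lat GeoJSON with properties
#' `segment_id`, `name`, `cfcc`, `avg_speed`; a projection centre converts to
#' and from the projected frame used for matching.
#'
#' @param path GeoJSON file path.
#' @param proj_center `c(lat0, lon0)` used by [project_local()].
#' @return `read_segments_geojson()`: segment tibble with `polyline` matrices
#'   in metres.
#' @export
read_segments_geojson <- function(path, proj_center) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  tibble(
    segment_id = purrr::map_int(feats, ~ as.integer(.x$properties$segment_id)),
    name = purrr::map_chr(feats, ~ .x$properties$name),
    cfcc = purrr::map_chr(feats, ~ .x$properties$cfcc),
    avg_speed = purrr::map_dbl(feats, ~ as.numeric(.x$properties$avg_speed)),
    polyline = purrr::map(feats, function(f) {
      ll <- do.call(rbind, lapply(f$geometry$coordinates, function(p) c(p[[1]], p[[2]])))
      lonlat_to_xy(ll[, 2], ll[, 1], proj_center)
    })
  )
}

#' @rdname read_segments_geojson
#' @param segments Segment tibble.
#' @export
write_segments_geojson <- function(segments, path, proj_center) {
  feats <- purrr::map(seq_len(nrow(segments)), function(i) {
    pl <- segments$polyline[[i]]
    ll <- unproject_local(pl[, 1], pl[, 2], proj_center)
    list(
      type = "Feature",
      properties = list(
        segment_id = segments$segment_id[i], name = segments$name[i],
        cfcc = segments$cfcc[i], avg_speed = segments$avg_speed[i]
      ),
      geometry = list(
        type = "LineString",
        coordinates = purrr::map(seq_len(nrow(pl)),
                                 ~ c(ll$longitude[.x], ll$latitude[.x]))
      )
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
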