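#' Load time-zone polygons from GeoJSON
#'
#' Reads a GeoJSON `FeatureCollection` of `Polygon` features with a `tz_id`
#' property (an IANA zone name). The package ships
#' `tz_us_simplified.geojson`, a deliberately SIMPLIFIED meridian-slab
#' approximation of the four CONUS zones intended for synthetic data and
#' tests; supply real boundary polygons for production use.
#'
#' @param path GeoJSON file; default is the packaged simplified set.
#' @return Tibble with `tz_id` and list-column `ring` (n x 2 lon/lat matrix).
#' @export
load_tz_polygons <- function(path = system.file("extdata", "tz_us_simplified.geojson",
                                                package = "drivecrumb")) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  tibble(
    tz_id = purrr::map_chr(feats, ~ .x$properties$tz_id),
    ring = purrr::map(feats, function(f) {
      ring <- f$geometry$coordinates[[1]]
      m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
      # drop closing vertex if repeated
      if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
      m
    })
  )
}

#' Default fast-path bounding box for the Central zone
#'
#' Points inside this rectangle are assigned `America/Chicago` without a
#' polygon lookup; it lies well inside the zone interior so the shortcut can
#' never disagree with the polygon result. Override via the pipeline config.
#'
#' @return Named list `lat_min`, `lat_max`, `lon_min`, `lon_max`, `tz_id`.
#' @export
central_fast_bbox <- function() {
  list(lat_min = 29.0, lat_max = 46.5, lon_min = -96.5, lon_max = -90.5,
       tz_id = "America/Chicago")
}

#' Resolve the IANA time zone of coordinates
#'
#' Points inside `fast_bbox` get its zone directly; all others fall back to
#' point-in-polygon lookup against `tz_polygons`. Points in no polygon
#' (offshore, outside coverage) resolve to `NA` and are excluded from
#' local-time analyses downstream.
#'
#' @param lat,lon Numeric vectors (decimal degrees).
#' @param tz_polygons Tibble from [load_tz_polygons()].
#' @param fast_bbox Fast-path rectangle, or `NULL` to disable.
#' @return Character vector of IANA zone names (`NA` when unresolved).
#' @export
lookup_time_zone <- function(lat, lon, tz_polygons = load_tz_polygons(),
                             fast_bbox = central_fast_bbox()) {
  out <- rep(NA_character_, length(lat))
  todo <- is.finite(lat) & is.finite(lon)
  if (!is.null(fast_bbox)) {
    fast <- todo &
      lat >= fast_bbox$lat_min & lat <= fast_bbox$lat_max &
      lon >= fast_bbox$lon_min & lon <= fast_bbox$lon_max
    out[fast] <- fast_bbox$tz_id
    todo <- todo & !fast
  }
  if (any(todo)) {
    ii <- which(todo)
    for (r in seq_len(nrow(tz_polygons))) {
      if (length(ii) == 0) break
      ring <- tz_polygons$ring[[r]]
      hit <- point_in_ring(lon[ii], lat[ii], ring)
      out[ii[hit]] <- tz_polygons$tz_id[r]
      ii <- ii[!hit]
    }
  }
  out
}

#' Convert UTC instants to local civil time
#'
#' Thin, explicit wrapper over the tz database: the returned `POSIXct` denotes
#' the same instants rendered in `tz_id`'s rules (standard/daylight offsets
#' included); converting back to UTC is the identity.
#'
#' @param timestamp_utc `POSIXct` vector (UTC).
#' @param tz_id Single IANA zone name.
#' @return `POSIXct` in `tz_id`.
#' @export
to_local <- function(timestamp_utc, tz_id) {
  stopifnot(length(tz_id) == 1, !is.na(tz_id))
  lubridate::with_tz(timestamp_utc, tz_id)
}

#' Localize breadcrumbs
#'
#' Adds `tz_id`, local calendar fields (`local_date`, `local_month`,
#' `local_hour`) computed under each crumb's zone. Crumbs whose zone cannot
#' be resolved keep `NA` local fields.
#'
#' @param crumbs Breadcrumb tibble with `latitude`, `longitude`,
#'   `timestamp_utc`.
#' @inheritParams lookup_time_zone
#' @return The crumbs with localization columns added.
#' @export
localize_breadcrumbs <- function(crumbs, tz_polygons = load_tz_polygons(),
                                 fast_bbox = central_fast_bbox()) {
  crumbs$tz_id <- lookup_time_zone(crumbs$latitude, crumbs$longitude,
                                   tz_polygons, fast_bbox)
  crumbs$local_date <- as.Date(rep(NA, nrow(crumbs)))
  crumbs$local_month <- NA_character_
  crumbs$local_hour <- NA_real_
  for (zone in unique(stats::na.omit(crumbs$tz_id))) {
    sel <- which(crumbs$tz_id %in% zone)
    loc <- lubridate::with_tz(crumbs$timestamp_utc[sel], zone)
    crumbs$local_date[sel] <- lubridate::as_date(loc)
    crumbs$local_month[sel] <- format(loc, "%Y-%m")
    crumbs$local_hour[sel] <- lubridate::hour(loc) + lubridate::minute(loc) / 60 +
      lubridate::second(loc) / 3600
  }
  crumbs
}
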