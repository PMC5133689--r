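#' Pipeline configuration
#'
#' Every numeric analysis parameter in one place. Defaults are the study
#' conditions the pipeline emulates: 30-second breadcrumbs, 3-hour idle
#' pings, 20-ft aggregation distance with 3-point minimum clusters and a 10%
#' primary-location share, destination radii of 100/250/500 ft, overspeeding
#' at 6 mph or more above the posted-limit proxy, and braking/acceleration
#' thresholds of 8 and 10 mph in one second.
#'
#' @param ... Overrides of any default field.
#' @return List of class `profile_config`.
#' @export
profile_config <- function(...) {
  cfg <- list(
    sampling_interval_s = 30,
    idle_ping_interval_h = 3,
    aggregate_distance_ft = 20,
    min_cluster_size = 3,
    primary_share = 0.10,
    destination_radii_ft = c(100, 250, 500),
    overspeed_margin_mph = 6,
    braking_threshold_mphps = 8,
    accel_threshold_mphps = 10,
    bbox_lat_min = 24.5, bbox_lat_max = 49.5,
    bbox_lon_min = -125.0, bbox_lon_max = -66.9,
    fast_tz_lat_min = 29.0, fast_tz_lat_max = 46.5,
    fast_tz_lon_min = -96.5, fast_tz_lon_max = -90.5,
    fast_tz_id = "America/Chicago",
    max_snap_m = 100,
    period = "month",
    night_definition = "strict"
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) abort(paste0("unknown config field(s): ", paste(bad, collapse = ", ")))
  cfg <- utils::modifyList(cfg, over)
  validate_profile_config(cfg)
  structure(cfg, class = "profile_config")
}

validate_profile_config <- function(cfg) {
  pos <- c("sampling_interval_s", "idle_ping_interval_h", "aggregate_distance_ft",
           "min_cluster_size", "primary_share", "overspeed_margin_mph",
           "braking_threshold_mphps", "accel_threshold_mphps", "max_snap_m")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) abort(paste0(f, " must be positive"))
  }
  if (is.unsorted(cfg$destination_radii_ft, strictly = TRUE)) {
    abort("destination_radii_ft must be strictly increasing")
  }
  if (!cfg$period %in% c("month", "week")) abort("period must be 'month' or 'week'")
  if (!cfg$night_definition %in% c("strict", "not_day")) {
    abort("night_definition must be 'strict' or 'not_day'")
  }
  invisible(cfg)
}

#' Read and write flat key/value config files
#'
#' Plain `key = value` text (TOML-like scalars; numeric vectors as
#' comma-separated values, `#` comments). A config round-trips through
#' [write_config()] / [read_config()] unchanged.
#'
#' @param path File path.
#' @return `read_config()`: a `profile_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  out <- list()
  for (p in kv) {
    stopifnot(length(p) == 2)
    val <- p[2]
    parts <- trimws(strsplit(val, ",")[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[p[1]]] <- if (any(is.na(num))) paste(parts, collapse = ",") else num
  }
  do.call(profile_config, out)
}

#' @rdname read_config
#' @param config A `profile_config`.
#' @export
write_config <- function(config, path) {
  lines <- purrr::imap_chr(unclass(config), function(v, k) {
    sprintf("%s = %s", k, paste(format(v, scientific = FALSE, trim = TRUE),
                                collapse = ", "))
  })
  writeLines(lines, path)
  invisible(path)
}

#' Run the full profiling pipeline
#'
#' Ingest, clean, reconstruct trips, localize, classify light phases,
#' spatialize and assemble monthly driver profiles — the whole chain from
#' daily vendor files to profile tables. Street segments, when given, add
#' nearest-road annotation and recomputed overspeeding validation events.
#'
#' @param breadcrumb_paths,activity_paths Input CSV files.
#' @param segments Optional segment tibble (or GeoJSON path) for road
#'   matching.
#' @param config A [profile_config()].
#' @param tz_polygons Time-zone polygons ([load_tz_polygons()]).
#' @param out_dir Optional directory: writes cleaned tables, profiles
#'   (CSV/JSON), the cleaning report (JSON) and resolved config.
#' @param proj_center Optional `c(lat, lon)` projection centre; defaults to
#'   the median crumb position.
#' @return List: `profiles` (a `drivecrumb_profile`), `trips`,
#'   `crumbs`, `activity` (cleaned), `alerts`, `cleaning_report`,
#'   `overlap`, `config`.
#' @export
run_pipeline <- function(breadcrumb_paths, activity_paths, segments = NULL,
                         config = profile_config(),
                         tz_polygons = load_tz_polygons(),
                         out_dir = NULL, proj_center = NULL) {
  crumbs_raw <- read_breadcrumbs(breadcrumb_paths)
  activity_raw <- read_activity(activity_paths)
  if (nrow(crumbs_raw) == 0) abort("no breadcrumbs ingested (all files empty or rejected)")

  bbox <- list(lat_min = config$bbox_lat_min, lat_max = config$bbox_lat_max,
               lon_min = config$bbox_lon_min, lon_max = config$bbox_lon_max)
  cleaned <- clean_driving_data(crumbs_raw, activity_raw, bbox = bbox)
  crumbs <- assign_trip_ids(cleaned$crumbs)

  fast_bbox <- list(lat_min = config$fast_tz_lat_min, lat_max = config$fast_tz_lat_max,
                    lon_min = config$fast_tz_lon_min, lon_max = config$fast_tz_lon_max,
                    tz_id = config$fast_tz_id)
  crumbs <- localize_breadcrumbs(crumbs, tz_polygons, fast_bbox)
  crumbs <- project_local(crumbs, center = proj_center)

  if (!is.null(segments)) {
    if (is.character(segments)) {
      segments <- read_segments_geojson(segments, attr(crumbs, "proj_center"))
    }
    crumbs <- annotate_breadcrumbs(crumbs, segments, max_snap_m = config$max_snap_m)
  }

  trips <- reconstruct_trips(crumbs)
  trips <- classify_trip_light(trips, tz_polygons, fast_bbox)
  alerts <- extract_alerts(crumbs, cleaned$activity)

  profiles <- assemble_profile(
    trips, cleaned$activity, crumbs,
    defective_vehicles = cleaned$report$defective_vehicle_ids,
    destination_radii_ft = config$destination_radii_ft,
    primary_share = config$primary_share,
    link_distance_ft = config$aggregate_distance_ft,
    min_cluster_size = config$min_cluster_size
  )
  areas <- compute_driving_area(
    filter(crumbs, !.data$vehicle_id %in% cleaned$report$defective_vehicle_ids)
  )
  overlap <- if (any(!areas$degenerate)) overlap_metrics(areas) else NULL

  result <- list(profiles = profiles, trips = trips, crumbs = crumbs,
                 activity = cleaned$activity, alerts = alerts,
                 cleaning_report = cleaned$report, overlap = overlap,
                 config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prof_flat <- result$profiles %>%
    as_tibble() %>%
    select(-dplyr::any_of(c("driving_area_hull")))
  readr::write_csv(prof_flat, file.path(out_dir, "profiles.csv"))
  jsonlite::write_json(as.data.frame(prof_flat), file.path(out_dir, "profiles.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_csv(select(result$crumbs, -dplyr::any_of("crumbs")),
                   file.path(out_dir, "breadcrumbs_clean.csv"))
  readr::write_csv(select(result$trips, -"crumbs"), file.path(out_dir, "trips.csv"))
  readr::write_csv(result$activity, file.path(out_dir, "activity_clean.csv"))
  cleaning_report_json(result$cleaning_report, file.path(out_dir, "cleaning_report.json"))
  write_config(result$config, file.path(out_dir, "config_resolved.txt"))
  if (!is.null(result$overlap)) {
    readr::write_csv(result$overlap$overall, file.path(out_dir, "overlap_overall.csv"))
    readr::write_csv(result$overlap$pairwise, file.path(out_dir, "overlap_pairwise.csv"))
  }
  hulls_geojson(result$profiles, result$crumbs,
                file.path(out_dir, "driving_areas.geojson"))
  invisible(out_dir)
}

hulls_geojson <- function(profiles, crumbs, path) {
  center <- attr(crumbs, "proj_center")
  if (is.null(center)) return(invisible(NULL))
  rows <- which(!purrr::map_lgl(profiles$driving_area_hull, is.null))
  feats <- purrr::map(rows, function(i) {
    h <- profiles$driving_area_hull[[i]]
    ll <- unproject_local(h[, 1], h[, 2], center)
    ring <- purrr::map(seq_len(nrow(h) + 1), function(k) {
      k <- if (k > nrow(h)) 1 else k
      c(ll$longitude[k], ll$latitude[k])
    })
    list(
      type = "Feature",
      properties = list(vehicle_id = profiles$vehicle_id[i],
                        local_month = profiles$local_month[i],
                        area_km2 = profiles$driving_area_km2[i]),
      geometry = list(type = "Polygon", coordinates = list(ring))
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats), path,
                       auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Summary report tables from assembled profiles
#'
#' Tabular equivalents of the study's figure panels: unique destinations by
#' radius, day/night trip counts, alert totals, all per driver-month with
#' explicit rows for gap months; plus per-driver grand totals that are
#' consistent with the monthly components by construction.
#'
#' @param profiles A `drivecrumb_profile` tibble.
#' @return List of tibbles: `destinations`, `light`, `alerts`, `totals`.
#' @export
report_profiles <- function(profiles) {
  p <- as_tibble(profiles)
  list(
    destinations = select(p, "vehicle_id", "local_month",
                          dplyr::starts_with("n_destinations_")),
    light = select(p, "vehicle_id", "local_month", "n_trips", "n_trips_day",
                   "n_trips_dawn", "n_trips_dusk", "n_trips_night",
                   "n_trips_not_day"),
    alerts = select(p, "vehicle_id", "local_month", "n_hard_braking",
                    "n_sudden_accel", "n_overspeeding"),
    totals = p %>%
      group_by(.data$vehicle_id) %>%
      summarise(
        n_months = n(),
        n_trips = sum(.data$n_trips, na.rm = TRUE),
        n_trips_night = sum(.data$n_trips_night, na.rm = TRUE),
        n_alerts = sum(.data$n_hard_braking + .data$n_sudden_accel +
                         .data$n_overspeeding, na.rm = TRUE),
        total_miles = sum(.data$total_miles, na.rm = TRUE),
        driving_hours = sum(.data$driving_hours, na.rm = TRUE),
        .groups = "drop"
      )
  )
}
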