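#' Count trips by light phase per driver-month
#'
#' Tabulates classified trips into day/dawn/dusk/night counts per driver and
#' local month. Months inside `month_range` with zero trips appear as
#' explicit zero rows, never as absent rows. The four phase counts always sum
#' to `n_trips`; `n_trips_not_day` is the combined dawn+dusk+night tally some
#' report tables prefer as a wide "night" definition.
#'
#' @param trips Classified trip tibble (see [classify_trip_light()]); only
#'   rows with a resolved `sun_phase` are counted.
#' @param month_range Optional character vector of `"YYYY-MM"` labels to
#'   zero-fill; defaults to the months spanned by the data.
#' @return Tibble: `vehicle_id`, `local_month`, `n_trips`, `n_trips_day`,
#'   `n_trips_dawn`, `n_trips_dusk`, `n_trips_night`, `n_trips_not_day`.
#' @export
count_trips_by_light <- function(trips, month_range = NULL) {
  work <- filter(trips, !is.na(.data$sun_phase), !is.na(.data$local_month))
  counts <- work %>%
    count(.data$vehicle_id, .data$local_month, .data$sun_phase) %>%
    tidyr::pivot_wider(names_from = "sun_phase", values_from = "n",
                       values_fill = 0L)
  for (ph in c("day", "dawn", "dusk", "night")) {
    if (!ph %in% names(counts)) counts[[ph]] <- 0L
  }
  if (is.null(month_range)) month_range <- month_seq(work$local_month)
  tidyr::expand_grid(
    vehicle_id = unique(trips$vehicle_id),
    local_month = month_range
  ) %>%
    left_join(counts, by = c("vehicle_id", "local_month")) %>%
    mutate(across(all_of(c("day", "dawn", "dusk", "night")),
                  ~ dplyr::coalesce(.x, 0L))) %>%
    mutate(
      n_trips = .data$day + .data$dawn + .data$dusk + .data$night,
      n_trips_not_day = .data$dawn + .data$dusk + .data$night
    ) %>%
    rename(n_trips_day = "day", n_trips_dawn = "dawn",
           n_trips_dusk = "dusk", n_trips_night = "night") %>%
    select("vehicle_id", "local_month", "n_trips", "n_trips_day",
           "n_trips_dawn", "n_trips_dusk", "n_trips_night", "n_trips_not_day")
}

month_seq <- function(months) {
  months <- stats::na.omit(unique(months))
  if (length(months) == 0) return(character(0))
  d <- seq(lubridate::ym(min(months)), lubridate::ym(max(months)), by = "month")
  format(d, "%Y-%m")
}

# Match each reconstructed trip to its activity row by vehicle and nearest
# start time within tolerance. Returns trip_id -> activity row index.
match_trips_activity_rows <- function(trips, activity, tol_s = 60) {
  out <- purrr::map_dfr(seq_len(nrow(trips)), function(i) {
    cand <- which(activity$vehicle_id == trips$vehicle_id[i])
    if (length(cand) == 0) return(NULL)
    dt <- abs(as.numeric(difftime(activity$start_time_utc[cand],
                                  trips$start_time[i], units = "secs")))
    j <- which.min(dt)
    if (dt[j] > tol_s) return(NULL)
    tibble(trip_id = trips$trip_id[i], act_row = cand[j])
  })
  if (nrow(out) == 0) out <- tibble(trip_id = character(), act_row = integer())
  out
}

#' Per-driver study-window totals and cohort summary
#'
#' `trip_statistics()` computes per-driver totals over the analysis window,
#' with column names mirroring the deposited five-month summary-table legend:
#' `numofdays`, `numtripsover5mo`, `trips_at_night5mo`, `trips_w_HB5mo`,
#' `trips_w_SA5mo`, `trips_speeding5mo`, `hours_speeding5mo`,
#' `tot_dist_driven5mo`, `tot_drv_hrs5mo`, `avg_trip_miles5mo`,
#' `avg_trip_mins5mo`. Distance, duration and alert counts come from the
#' activity rows matched to usable trips; night trips from the phase
#' classification (strict night).
#'
#' `cohort_summary()` reduces the per-driver table to cohort mean and sample
#' standard deviation (n - 1 denominator) per metric.
#'
#' @param trips Classified trip tibble ([classify_trip_light()] on
#'   [reconstruct_trips()] output); only `usable` trips are counted.
#' @param activity Cleaned trip-record tibble.
#' @param match_tolerance_s Trip/activity start-time matching tolerance (s).
#' @return One row per driver (`id` column), class `drivecrumb_driver_stats`.
#' @export
trip_statistics <- function(trips, activity, match_tolerance_s = 60) {
  trips <- filter(trips, .data$usable)
  m <- match_trips_activity_rows(trips, activity, match_tolerance_s)
  per_trip <- trips %>%
    left_join(m, by = "trip_id") %>%
    mutate(
      distance = activity$distance[.data$act_row],
      duration_s = activity$duration_s[.data$act_row],
      n_hard_braking = activity$n_hard_braking[.data$act_row],
      n_sudden_accel = activity$n_sudden_accel[.data$act_row],
      n_overspeeding = activity$n_overspeeding[.data$act_row],
      overspeeding_duration_s = activity$overspeeding_duration_s[.data$act_row]
    )
  out <- per_trip %>%
    group_by(id = .data$vehicle_id) %>%
    summarise(
      numofdays = dplyr::n_distinct(lubridate::as_date(.data$start_time)),
      numtripsover5mo = n(),
      trips_at_night5mo = sum(.data$sun_phase %in% "night"),
      trips_w_HB5mo = sum(dplyr::coalesce(.data$n_hard_braking, 0L) > 0),
      trips_w_SA5mo = sum(dplyr::coalesce(.data$n_sudden_accel, 0L) > 0),
      trips_speeding5mo = sum(dplyr::coalesce(.data$n_overspeeding, 0L) > 0),
      hours_speeding5mo = sum(dplyr::coalesce(.data$overspeeding_duration_s, 0)) / 3600,
      tot_dist_driven5mo = sum(dplyr::coalesce(.data$distance, 0)),
      tot_drv_hrs5mo = sum(dplyr::coalesce(.data$duration_s, 0)) / 3600,
      .groups = "drop"
    ) %>%
    mutate(
      avg_trip_miles5mo = .data$tot_dist_driven5mo / .data$numtripsover5mo,
      avg_trip_mins5mo = .data$tot_drv_hrs5mo * 60 / .data$numtripsover5mo
    )
  class(out) <- c("drivecrumb_driver_stats", class(out))
  out
}

#' @rdname trip_statistics
#' @param stats A `drivecrumb_driver_stats` table (or any tibble of
#'   per-driver numeric metrics with an `id` column).
#' @export
cohort_summary <- function(stats) {
  stats %>%
    select(-dplyr::any_of("id")) %>%
    tidyr::pivot_longer(dplyr::everything(), names_to = "metric") %>%
    group_by(.data$metric) %>%
    summarise(
      n = sum(!is.na(.data$value)),
      mean = mean(.data$value, na.rm = TRUE),
      sd = sd(.data$value, na.rm = TRUE),
      .groups = "drop"
    )
}

#' Read a per-participant five-month summary table
#'
#' Reads a CSV in the deposited summary-table schema (`id`, `numofdays`,
#' `numtripsover5mo`, `trips_at_night5mo`, `trips_w_HB5mo`, `trips_w_SA5mo`,
#' `trips_speeding5mo`, `hours_speeding5mo`, `tot_dist_driven5mo`,
#' `tot_drv_hrs5mo`, `avg_trip_miles5mo`, `avg_trip_mins5mo`) as a
#' `drivecrumb_driver_stats` table, ready for [cohort_summary()]. The study's
#' own deposited table is not distributed with the package; users who obtain
#' it can drop it at `inst/extdata/dataset1.csv` (or pass any path).
#'
#' @param path CSV file path.
#' @return A `drivecrumb_driver_stats` tibble.
#' @export
read_driver_summary <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  if (!"id" %in% names(out)) abort("driver summary table needs an 'id' column")
  class(out) <- c("drivecrumb_driver_stats", class(out))
  out
}

#' Assemble per-driver per-month driving profiles
#'
#' Joins the temporal (phase counts), behavioral (alert totals and
#' alert-trip counts) and activity-derived (miles, hours) components into one
#' row per driver-month, with the spatial components (primary locations,
#' driving area, mean center, destination counts) attached where available.
#' Missing components are explicit `NA`s; drivers flagged for defective
#' devices get fully `NA`-marked metric columns with
#' `excluded_reason = "defective_device"`.
#'
#' @param trips Classified trip tibble.
#' @param activity Cleaned activity tibble.
#' @param crumbs Cleaned, localized, projected breadcrumb tibble (needs `x`,
#'   `y`, `local_month`, `trip_id`, `event_type`).
#' @param defective_vehicles Character vector of vehicles to null-mark.
#' @param destination_radii_ft Radii for [count_unique_destinations()].
#' @param primary_share,link_distance_ft,min_cluster_size Primary-location
#'   parameters (defaults 0.10, 20 ft, 3).
#' @param match_tolerance_s Trip/activity matching tolerance (s).
#' @return Tibble of class `drivecrumb_profile`, one row per driver-month.
#' @export
assemble_profile <- function(trips, activity, crumbs,
                             defective_vehicles = character(0),
                             destination_radii_ft = c(100, 250, 500),
                             primary_share = 0.10, link_distance_ft = 20,
                             min_cluster_size = 3, match_tolerance_s = 60) {
  usable <- filter(trips, .data$usable)
  light <- count_trips_by_light(usable)
  m <- match_trips_activity_rows(usable, activity, match_tolerance_s)
  per_trip <- usable %>%
    left_join(m, by = "trip_id") %>%
    mutate(
      distance = activity$distance[.data$act_row],
      duration_s = activity$duration_s[.data$act_row],
      n_hb = dplyr::coalesce(activity$n_hard_braking[.data$act_row], 0L),
      n_sa = dplyr::coalesce(activity$n_sudden_accel[.data$act_row], 0L),
      n_os = dplyr::coalesce(activity$n_overspeeding[.data$act_row], 0L)
    )
  behav <- per_trip %>%
    group_by(.data$vehicle_id, .data$local_month) %>%
    summarise(
      n_hard_braking = sum(.data$n_hb),
      n_sudden_accel = sum(.data$n_sa),
      n_overspeeding = sum(.data$n_os),
      trips_w_hard_braking = sum(.data$n_hb > 0),
      trips_w_sudden_accel = sum(.data$n_sa > 0),
      trips_w_overspeeding = sum(.data$n_os > 0),
      total_miles = sum(dplyr::coalesce(.data$distance, 0)),
      driving_hours = sum(dplyr::coalesce(.data$duration_s, 0)) / 3600,
      .groups = "drop"
    )

  spatial <- spatial_components(crumbs, destination_radii_ft, primary_share,
                                link_distance_ft, min_cluster_size)

  out <- light %>%
    left_join(behav, by = c("vehicle_id", "local_month")) %>%
    left_join(spatial$areas, by = c("vehicle_id", "local_month")) %>%
    left_join(spatial$centers, by = c("vehicle_id", "local_month")) %>%
    left_join(spatial$destinations, by = c("vehicle_id", "local_month")) %>%
    mutate(
      across(all_of(c("n_hard_braking", "n_sudden_accel", "n_overspeeding",
                      "trips_w_hard_braking", "trips_w_sudden_accel",
                      "trips_w_overspeeding")),
             ~ dplyr::coalesce(.x, 0L)),
      total_miles = dplyr::coalesce(.data$total_miles, 0),
      driving_hours = dplyr::coalesce(.data$driving_hours, 0),
      mean_miles_per_trip = if_else(.data$n_trips > 0,
                                    .data$total_miles / .data$n_trips, NA_real_),
      excluded_reason = if_else(.data$vehicle_id %in% defective_vehicles,
                                "defective_device", NA_character_)
    )
  metric_cols <- setdiff(names(out),
                         c("vehicle_id", "local_month", "excluded_reason"))
  for (col in metric_cols) {
    out[[col]][!is.na(out$excluded_reason)] <- NA
  }
  attr(out, "primary_locations") <- spatial$primaries
  class(out) <- c("drivecrumb_profile", class(out))
  out
}

spatial_components <- function(crumbs, radii_ft, primary_share,
                               link_distance_ft, min_cluster_size) {
  has_month <- filter(crumbs, !is.na(.data$local_month))
  areas <- compute_driving_area(has_month) %>%
    select("vehicle_id", "local_month", driving_area_km2 = "area_km2",
           driving_area_degenerate = "degenerate", driving_area_hull = "hull")
  centers <- compute_mean_center(has_month, proj_center = attr(crumbs, "proj_center")) %>%
    select("vehicle_id", "local_month", mean_center_x = "x", mean_center_y = "y",
           dplyr::any_of(c(mean_center_lat = "latitude", mean_center_lon = "longitude")))
  ign <- filter(has_month, .data$event_type == "ignition_on")
  destinations <- count_unique_destinations(
    ign, radii_ft = radii_ft, group_cols = c("vehicle_id", "local_month")
  ) %>%
    mutate(radius_ft = paste0("n_destinations_", .data$radius_ft, "ft")) %>%
    tidyr::pivot_wider(names_from = "radius_ft", values_from = "n_destinations")
  primaries <- purrr::map_dfr(
    split(ign, ign$vehicle_id),
    function(df) {
      cl <- suppressWarnings(cluster_ignition_points(
        df, link_distance_m = link_distance_ft * M_PER_FT,
        min_size = min_cluster_size
      ))
      pl <- detect_primary_locations(cl, share_threshold = primary_share)
      if (nrow(pl) == 0) return(NULL)
      mutate(pl, vehicle_id = df$vehicle_id[1], .before = 1)
    }
  )
  list(areas = areas, centers = centers, destinations = destinations,
       primaries = primaries)
}

#' @export
print.drivecrumb_profile <- function(x, ...) {
  cat(sprintf("<driving profiles: %d driver-month rows, %d driver(s)>\n",
              nrow(x), dplyr::n_distinct(x$vehicle_id)))
  NextMethod()
}

#' Tidy a driving-profile table into long metric form
#'
#' @param x A `drivecrumb_profile`.
#' @param ... Unused.
#' @return Long tibble: `vehicle_id`, `local_month`, `metric`, `value`.
#' @export
tidy.drivecrumb_profile <- function(x, ...) {
  x %>%
    as_tibble() %>%
    select(-dplyr::any_of(c("driving_area_hull", "excluded_reason",
                            "driving_area_degenerate"))) %>%
    tidyr::pivot_longer(-c("vehicle_id", "local_month"),
                        names_to = "metric", values_to = "value",
                        values_transform = as.numeric)
}

#' Cohort-level glance at a driving-profile table
#'
#' @inheritParams tidy.drivecrumb_profile
#' @return One row: drivers, months, trips, alert totals and mean monthly
#'   driving-area.
#' @export
glance.drivecrumb_profile <- function(x, ...) {
  tibble(
    n_drivers = dplyr::n_distinct(x$vehicle_id),
    n_months = dplyr::n_distinct(x$local_month),
    n_trips = sum(x$n_trips, na.rm = TRUE),
    n_trips_night = sum(x$n_trips_night, na.rm = TRUE),
    n_alerts = sum(x$n_hard_braking + x$n_sudden_accel + x$n_overspeeding,
                   na.rm = TRUE),
    mean_driving_area_km2 = mean(x$driving_area_km2, na.rm = TRUE)
  )
}
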