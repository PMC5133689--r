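#' Continental-US bounding box
#'
#' Default envelope used by [filter_coordinates()]. Values are a standard
#' CONUS rectangle; override for studies outside the continental US.
#'
#' @return Named list with `lat_min`, `lat_max`, `lon_min`, `lon_max`.
#' @export
conus_bbox <- function() {
  list(lat_min = 24.5, lat_max = 49.5, lon_min = -125.0, lon_max = -66.9)
}

#' Remove breadcrumbs with invalid or out-of-area coordinates
#'
#' Device connect/disconnect glitches report (0, 0) fixes, and satellite-lock
#' failures can report wildly wrong positions (the classic symptom is a fix on
#' another continent). Rows outside the bounding box, exactly (0, 0), or with
#' non-finite coordinates are removed. Because a bad fix makes the whole trip's
#' location uncertain, every breadcrumb sharing a removed crumb's trip is
#' removed too (reason `trip_contaminated`).
#'
#' The zero test is exact equality on either coordinate — the device-fault
#' signature — not an epsilon ball.
#'
#' @param crumbs Breadcrumb tibble. If it has no `trip_id` column, provisional
#'   trip ids are assigned with [assign_trip_ids()] for trip-scoped removal.
#' @param bbox Bounding box as from [conus_bbox()].
#' @return A list with `kept` and `removed` tibbles (`removed` gains a
#'   `reason` column) and a one-row `report` of counts. `kept` + `removed`
#'   partition the input.
#' @export
filter_coordinates <- function(crumbs, bbox = conus_bbox()) {
  if (nrow(crumbs) == 0) {
    return(filter_result(crumbs, crumbs[0, ], character(0), "filter_coordinates"))
  }
  had_trip <- "trip_id" %in% names(crumbs)
  work <- if (had_trip) crumbs else assign_trip_ids(crumbs)

  zero <- (work$latitude == 0) | (work$longitude == 0)
  zero[is.na(zero)] <- FALSE
  nonfinite <- !is.finite(work$latitude) | !is.finite(work$longitude)
  outside <- !nonfinite & !zero & (
    work$latitude < bbox$lat_min | work$latitude > bbox$lat_max |
      work$longitude < bbox$lon_min | work$longitude > bbox$lon_max
  )
  reason <- rep(NA_character_, nrow(work))
  reason[outside] <- "outside_bbox"
  reason[nonfinite] <- "nonfinite_coordinates"
  reason[zero] <- "zero_coordinates"

  bad_trip <- unique(work$trip_id[!is.na(reason) & !is.na(work$trip_id)])
  contaminated <- is.na(reason) & !is.na(work$trip_id) & work$trip_id %in% bad_trip
  reason[contaminated] <- "trip_contaminated"

  keep <- is.na(reason)
  kept <- work[keep, , drop = FALSE]
  removed <- mutate(work[!keep, , drop = FALSE], reason = reason[!keep])
  if (!had_trip) {
    kept$trip_id <- NULL
    kept$trip_role <- NULL
  }
  filter_result(kept, removed, reason[!keep], "filter_coordinates")
}

#' Drop repeated timestamps per vehicle
#'
#' Cleaning criterion: no two observations of the same vehicle may share a
#' timestamp. The first occurrence in file order is kept. Duplicates whose
#' coordinates differ from the kept row (i.e. not byte-identical repeats) are
#' additionally flagged `conflict = TRUE` for review.
#'
#' @param crumbs Breadcrumb tibble.
#' @return List with `kept`, `removed` (with `reason = "duplicate_timestamp"`
#'   and `conflict` flag) and `report`.
#' @export
dedupe_timestamps <- function(crumbs) {
  if (nrow(crumbs) == 0) {
    return(filter_result(crumbs, crumbs[0, ], character(0), "dedupe_timestamps"))
  }
  key <- paste(crumbs$vehicle_id, fmt_utc(crumbs$timestamp_utc))
  dup <- duplicated(key)
  kept <- crumbs[!dup, , drop = FALSE]
  removed <- crumbs[dup, , drop = FALSE]
  if (nrow(removed) > 0) {
    first_lat <- crumbs$latitude[!dup][match(key[dup], key[!dup])]
    first_lon <- crumbs$longitude[!dup][match(key[dup], key[!dup])]
    removed <- mutate(removed,
      reason = "duplicate_timestamp",
      conflict = !(near_or_both_na(.data$latitude, first_lat) &
                     near_or_both_na(.data$longitude, first_lon))
    )
  } else {
    removed$reason <- character(0)
    removed$conflict <- logical(0)
  }
  filter_result(kept, removed, removed$reason, "dedupe_timestamps")
}

near_or_both_na <- function(x, y) {
  (is.na(x) & is.na(y)) | (!is.na(x) & !is.na(y) & x == y)
}

#' Remove malformed trip records
#'
#' Trip rows with `NA` end coordinates (GPS signal loss at trip end, or an
#' "abandoned" duplicate trip start) or a zero start coordinate (device fault)
#' are removed. Kept trips have finite, nonzero endpoints.
#'
#' @param activity Trip-record tibble from [read_activity()].
#' @return List with `kept`, `removed` (reasons `na_end`, `na_start`,
#'   `zero_start`, `zero_end`) and `report`.
#' @export
filter_trips <- function(activity) {
  if (nrow(activity) == 0) {
    return(filter_result(activity, activity[0, ], character(0), "filter_trips"))
  }
  reason <- rep(NA_character_, nrow(activity))
  zero_end <- activity$end_lat %in% 0 | activity$end_lon %in% 0
  zero_start <- activity$start_lat %in% 0 | activity$start_lon %in% 0
  na_start <- is.na(activity$start_lat) | is.na(activity$start_lon)
  na_end <- is.na(activity$end_lat) | is.na(activity$end_lon)
  reason[zero_end] <- "zero_end"
  reason[zero_start] <- "zero_start"
  reason[na_start] <- "na_start"
  reason[na_end] <- "na_end"
  keep <- is.na(reason)
  removed <- mutate(activity[!keep, , drop = FALSE], reason = reason[!keep])
  filter_result(activity[keep, , drop = FALSE], removed, reason[!keep], "filter_trips")
}

#' Flag vehicles with defective GPS devices
#'
#' A failing device can report zero coordinates for weeks at a time. A vehicle
#' is flagged when, within any rolling window of `window_days`, more than
#' `zero_fraction` of its breadcrumbs (and at least `min_crumbs` of them) have
#' a zero coordinate. Flagged vehicles should be excluded from profile
#' computation.
#'
#' @param crumbs Breadcrumb tibble.
#' @param window_days Rolling window length in days (default 7).
#' @param zero_fraction Fraction of zero-coordinate crumbs above which the
#'   window is defective (default 0.5).
#' @param min_crumbs Minimum crumbs in a window before it can flag (default
#'   25), so an isolated zero fix never flags a vehicle.
#' @return Character vector of flagged vehicle ids.
#' @export
flag_defective_devices <- function(crumbs, window_days = 7, zero_fraction = 0.5,
                                   min_crumbs = 25) {
  if (nrow(crumbs) == 0) return(character(0))
  crumbs %>%
    mutate(
      day = lubridate::as_date(.data$timestamp_utc),
      zero = (.data$latitude %in% 0) | (.data$longitude %in% 0)
    ) %>%
    group_by(.data$vehicle_id, .data$day) %>%
    summarise(n = n(), nz = sum(.data$zero), .groups = "drop") %>%
    group_by(.data$vehicle_id) %>%
    summarise(defective = any_window_defective(.data$day, .data$n, .data$nz,
                                               window_days, zero_fraction, min_crumbs),
              .groups = "drop") %>%
    filter(.data$defective) %>%
    pull("vehicle_id")
}

any_window_defective <- function(day, n, nz, window_days, zero_fraction, min_crumbs) {
  days <- seq(min(day), max(day), by = "day")
  n_full <- nz_full <- rep(0, length(days))
  idx <- match(day, days)
  n_full[idx] <- n
  nz_full[idx] <- nz
  cs_n <- cumsum(n_full)
  cs_z <- cumsum(nz_full)
  w <- min(window_days, length(days))
  starts <- seq_len(length(days) - w + 1)
  tot <- cs_n[starts + w - 1] - c(0, cs_n)[starts]
  zer <- cs_z[starts + w - 1] - c(0, cs_z)[starts]
  any(tot >= min_crumbs & zer / pmax(tot, 1) > zero_fraction)
}

filter_result <- function(kept, removed, reasons, step) {
  report <- tibble(
    step = step,
    n_input = nrow(kept) + nrow(removed),
    n_kept = nrow(kept),
    n_removed = nrow(removed)
  )
  list(kept = kept, removed = removed, report = report)
}

#' Run the full breadcrumb/activity cleaning pipeline
#'
#' Applies the cleaning criteria in the documented order — coordinate
#' validation (with whole-trip removal), timestamp de-duplication, trip-record
#' filtering — and assembles a cleaning-report audit. Every removed row
#' carries exactly one reason.
#'
#' @param crumbs Breadcrumb tibble from [read_breadcrumbs()].
#' @param activity Trip-record tibble from [read_activity()].
#' @param bbox Coordinate envelope, default [conus_bbox()].
#' @param flag_devices If `TRUE` (default), run [flag_defective_devices()] on
#'   the raw crumbs and record flagged vehicles in the report (rows are not
#'   dropped here; exclusion is a profile-stage decision).
#' @return List with `crumbs`, `activity` (cleaned tibbles), `removed_crumbs`,
#'   `removed_trips` (with reasons) and `report` (class
#'   `drivecrumb_cleaning_report`).
#' @export
clean_driving_data <- function(crumbs, activity, bbox = conus_bbox(),
                               flag_devices = TRUE) {
  defective <- if (flag_devices) flag_defective_devices(crumbs) else character(0)
  f1 <- filter_coordinates(crumbs, bbox)
  f2 <- dedupe_timestamps(f1$kept)
  f3 <- filter_trips(activity)
  removed_crumbs <- bind_rows(f1$removed, mutate(f2$removed, conflict = NULL))
  conflicts <- if (nrow(f2$removed) > 0) sum(f2$removed$conflict) else 0L
  report <- structure(
    list(
      n_input_crumbs = nrow(crumbs),
      n_input_trips = nrow(activity),
      n_removed_coordinates = nrow(f1$removed),
      n_removed_duplicates = nrow(f2$removed),
      n_duplicate_conflicts = as.integer(conflicts),
      n_trips_removed = nrow(f3$removed),
      crumb_reason_counts = table_to_tibble(removed_crumbs$reason),
      trip_reason_counts = table_to_tibble(f3$removed$reason),
      defective_vehicle_ids = defective,
      steps = bind_rows(f1$report, f2$report, f3$report)
    ),
    class = "drivecrumb_cleaning_report"
  )
  list(
    crumbs = f2$kept, activity = f3$kept,
    removed_crumbs = removed_crumbs, removed_trips = f3$removed,
    report = report
  )
}

table_to_tibble <- function(reason) {
  if (length(reason) == 0) return(tibble(reason = character(), n = integer()))
  as_tibble(as.data.frame(table(reason = reason), stringsAsFactors = FALSE)) %>%
    rename(n = "Freq")
}

#' @export
print.drivecrumb_cleaning_report <- function(x, ...) {
  cat("<cleaning report>\n")
  cat(sprintf("  breadcrumbs: %d in, %d removed (coordinates %d, duplicates %d; %d conflicting)\n",
              x$n_input_crumbs, x$n_removed_coordinates + x$n_removed_duplicates,
              x$n_removed_coordinates, x$n_removed_duplicates, x$n_duplicate_conflicts))
  cat(sprintf("  trip records: %d in, %d removed\n", x$n_input_trips, x$n_trips_removed))
  if (length(x$defective_vehicle_ids) > 0) {
    cat("  defective devices:", paste(x$defective_vehicle_ids, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize a cleaning report to JSON
#'
#' @param report A `drivecrumb_cleaning_report`.
#' @param path Output path; when `NULL`, the JSON string is returned.
#' @export
cleaning_report_json <- function(report, path = NULL) {
  payload <- report
  class(payload) <- NULL
  payload$steps <- as.data.frame(payload$steps)
  payload$crumb_reason_counts <- as.data.frame(payload$crumb_reason_counts)
  payload$trip_reason_counts <- as.data.frame(payload$trip_reason_counts)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}
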