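#' Extract device-reported adverse-driving alerts
#'
#' Collects alert-typed breadcrumb rows (`overspeeding`, `hard_braking`,
#' `sudden_acceleration`) into one event list and reconciles per-trip counts
#' against the activity file's alert-count fields. Alert crumbs falling inside
#' no trip window are kept and flagged `orphan`. Count discrepancies between
#' the two channels are returned as an attribute, not silently dropped.
#'
#' @param crumbs Breadcrumb tibble, ideally with `trip_id` from
#'   [assign_trip_ids()] (assigned internally otherwise).
#' @param activity Optional trip-record tibble for reconciliation.
#' @param match_tolerance_s Activity rows are matched to reconstructed trips
#'   by vehicle and start time within this tolerance (default 60 s).
#' @return Tibble of events: `vehicle_id`, `kind`, `time_utc`, `latitude`,
#'   `longitude`, magnitude fields, `trip_id`, `orphan`, `source =
#'   "device_reported"`; attribute `discrepancies` holds per-trip count
#'   mismatches when `activity` is given.
#' @export
extract_alerts <- function(crumbs, activity = NULL, match_tolerance_s = 60) {
  if (!("trip_id" %in% names(crumbs))) crumbs <- assign_trip_ids(crumbs)
  ev <- crumbs %>%
    filter(.data$event_type %in% alert_event_types()) %>%
    mutate(
      kind = .data$event_type, time_utc = .data$timestamp_utc,
      orphan = is.na(.data$trip_id), source = "device_reported"
    ) %>%
    select("vehicle_id", "kind", "time_utc", "latitude", "longitude",
           "peak_speed", "avg_event_speed", "initial_speed", "final_speed",
           "trip_id", "orphan", "source")
  check_alert_invariants(ev)
  disc <- NULL
  if (!is.null(activity) && nrow(activity) > 0) {
    counted <- ev %>%
      filter(!.data$orphan) %>%
      count(.data$trip_id, .data$kind) %>%
      tidyr::pivot_wider(names_from = "kind", values_from = "n", values_fill = 0L)
    for (k in alert_event_types()) {
      if (!k %in% names(counted)) counted[[k]] <- 0L
    }
    trips <- crumbs %>%
      filter(.data$trip_role %in% "start") %>%
      select("trip_id", "vehicle_id", trip_start = "timestamp_utc")
    matched <- match_activity_trips(trips, activity, match_tolerance_s)
    disc <- matched %>%
      left_join(counted, by = "trip_id") %>%
      mutate(across(all_of(alert_event_types()), ~ dplyr::coalesce(.x, 0L))) %>%
      filter(
        .data$hard_braking != .data$n_hard_braking |
          .data$sudden_acceleration != .data$n_sudden_accel |
          .data$overspeeding != .data$n_overspeeding
      )
    if (nrow(disc) > 0) {
      inform(sprintf("%d trip(s) with breadcrumb/activity alert-count discrepancies",
                     nrow(disc)))
    }
  }
  structure(ev, discrepancies = disc)
}

# nearest-start matching of reconstructed trips to activity rows
match_activity_trips <- function(trips, activity, tol_s) {
  purrr::map_dfr(seq_len(nrow(activity)), function(i) {
    cand <- trips[trips$vehicle_id == activity$vehicle_id[i], ]
    if (nrow(cand) == 0) return(NULL)
    dt <- abs(as.numeric(difftime(cand$trip_start, activity$start_time_utc[i],
                                  units = "secs")))
    j <- which.min(dt)
    if (dt[j] > tol_s) return(NULL)
    tibble(
      trip_id = cand$trip_id[j], vehicle_id = activity$vehicle_id[i],
      n_hard_braking = activity$n_hard_braking[i],
      n_sudden_accel = activity$n_sudden_accel[i],
      n_overspeeding = activity$n_overspeeding[i]
    )
  })
}

check_alert_invariants <- function(ev) {
  bad_os <- ev$kind == "overspeeding" &
    !is.na(ev$peak_speed) & !is.na(ev$avg_event_speed) &
    ev$peak_speed < ev$avg_event_speed
  bad_hb <- ev$kind == "hard_braking" &
    !is.na(ev$initial_speed) & !is.na(ev$final_speed) &
    ev$initial_speed <= ev$final_speed
  bad_sa <- ev$kind == "sudden_acceleration" &
    !is.na(ev$initial_speed) & !is.na(ev$final_speed) &
    ev$final_speed <= ev$initial_speed
  n_bad <- sum(bad_os) + sum(bad_hb) + sum(bad_sa)
  if (n_bad > 0) warn(sprintf("%d alert event(s) violate speed-ordering invariants", n_bad))
  invisible(NULL)
}

#' Recompute overspeeding events from annotated crumbs
#'
#' Overspeeding is driving at least `margin_mph` (default 6) above the posted
#' limit, proxied by the matched road segment's average speed. One event is
#' emitted per maximal run of consecutive crumbs within a trip at or above
#' `road_avg_speed + margin_mph`; a single qualifying crumb constitutes an
#' event. This is a validation channel against the device-reported alerts —
#' the 30-s sampling bounds how faithfully excursion boundaries are located.
#'
#' @param crumbs Crumbs with `trip_id`, `speed` and `road_avg_speed` (see
#'   [annotate_breadcrumbs()]).
#' @param margin_mph Speed margin over the limit proxy (default 6).
#' @return Tibble of events: `vehicle_id`, `trip_id`, `kind = "overspeeding"`,
#'   `time_start`, `time_end`, `n_crumbs`, `peak_speed`, `avg_event_speed`,
#'   `source = "recomputed"`.
#' @export
recompute_overspeeding <- function(crumbs, margin_mph = 6) {
  work <- crumbs %>%
    filter(!is.na(.data$trip_id), !is.na(.data$speed),
           !is.na(.data$road_avg_speed)) %>%
    arrange(.data$vehicle_id, .data$timestamp_utc) %>%
    mutate(over = .data$speed >= .data$road_avg_speed + margin_mph)
  if (nrow(work) == 0 || !any(work$over)) return(empty_recomputed())
  work %>%
    group_by(.data$trip_id) %>%
    mutate(run = cumsum(.data$over & !dplyr::coalesce(lag(.data$over), FALSE))) %>%
    filter(.data$over) %>%
    group_by(.data$vehicle_id, .data$trip_id, .data$run) %>%
    summarise(
      time_start = min(.data$timestamp_utc), time_end = max(.data$timestamp_utc),
      n_crumbs = n(), peak_speed = max(.data$speed),
      avg_event_speed = mean(.data$speed), .groups = "drop"
    ) %>%
    mutate(kind = "overspeeding", source = "recomputed") %>%
    select("vehicle_id", "trip_id", "kind", "time_start", "time_end",
           "n_crumbs", "peak_speed", "avg_event_speed", "source")
}

empty_recomputed <- function() {
  tibble(
    vehicle_id = character(), trip_id = character(), kind = character(),
    time_start = lubridate::as_datetime(character()),
    time_end = lubridate::as_datetime(character()),
    n_crumbs = integer(), peak_speed = double(), avg_event_speed = double(),
    source = character()
  )
}

#' Recompute braking/acceleration events from a 1 Hz speed trace
#'
#' Hard braking is a decrease of at least `braking_threshold` mph in one
#' second; sudden acceleration an increase of at least `accel_threshold` mph
#' in one second (the vendor's "8 to 10 mph in one second" pair, mapped
#' decrease/increase respectively; set both to the same value for the
#' single-band reading). Consecutive qualifying seconds merge into one event.
#' This operates on 1-second traces (synthetic validation, instrumented
#' drives): 30-second breadcrumbs cannot certify 1-second deltas.
#'
#' @param trace Tibble with `t` (seconds or `POSIXct`, 1 Hz) and `speed`
#'   (mph).
#' @param braking_threshold,accel_threshold Thresholds in mph per second
#'   (defaults 8 and 10).
#' @return Tibble of events: `kind`, `t_start`, `t_end`, `initial_speed`,
#'   `final_speed`, `max_delta`.
#' @export
recompute_accel_events <- function(trace, braking_threshold = 8,
                                   accel_threshold = 10) {
  stopifnot(nrow(trace) >= 2)
  d <- diff(trace$speed)
  qual <- ifelse(d <= -braking_threshold, "hard_braking",
                 ifelse(d >= accel_threshold, "sudden_acceleration", NA))
  runs <- rle(ifelse(is.na(qual), "none", qual))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- which(runs$values != "none")
  purrr::map_dfr(keep, function(k) {
    i <- starts[k]; j <- ends[k]     # deltas i..j => samples i..j+1
    tibble(
      kind = runs$values[k],
      t_start = trace$t[i], t_end = trace$t[j + 1],
      initial_speed = trace$speed[i], final_speed = trace$speed[j + 1],
      max_delta = if (runs$values[k] == "hard_braking") min(d[i:j]) else max(d[i:j])
    )
  })
}
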