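#' Breadcrumb and activity file schemas
#'
#' The ingest schema mirrors the daily CSV feeds of commercial OBDII GPS
#' loggers: one breadcrumb row per 30-second fix, one activity row per trip.
#' `breadcrumb_cols()` and `activity_cols()` return the expected column names
#' in order; ingest rejects files whose header set does not match.
#'
#' @return Character vector of column names.
#' @export
breadcrumb_cols <- function() {
  c(
    "vehicle_id", "timestamp_utc", "latitude", "longitude", "speed",
    "odometer", "event_type", "nearest_address",
    "peak_speed", "avg_event_speed", "initial_speed", "final_speed"
  )
}

#' @rdname breadcrumb_cols
#' @export
activity_cols <- function() {
  c(
    "vehicle_id", "start_time_utc", "start_lat", "start_lon",
    "end_lat", "end_lon", "start_address", "end_address",
    "duration_s", "distance", "avg_speed", "max_speed",
    "n_sudden_accel", "n_hard_braking", "n_overspeeding",
    "overspeeding_duration_s"
  )
}

#' Known breadcrumb event-type codes
#'
#' Regular fixes, ignition on/off brackets, the three adverse-driving alerts,
#' 3-hour idle pings while parked, and device-health codes. Unknown codes are
#' preserved on ingest and flagged via `event_known`.
#'
#' @return Character vector of event-type codes.
#' @export
event_types <- function() {
  c(
    "regular", "ignition_on", "ignition_off",
    "hard_braking", "sudden_acceleration", "overspeeding",
    "idle_ping", "low_battery", "device_connect", "device_disconnect",
    "device_fault"
  )
}

alert_event_types <- function() {
  c("hard_braking", "sudden_acceleration", "overspeeding")
}

bc_col_types <- function() {
  readr::cols(
    vehicle_id = readr::col_character(),
    timestamp_utc = readr::col_character(),
    latitude = readr::col_double(),
    longitude = readr::col_double(),
    speed = readr::col_double(),
    odometer = readr::col_double(),
    event_type = readr::col_character(),
    nearest_address = readr::col_character(),
    peak_speed = readr::col_double(),
    avg_event_speed = readr::col_double(),
    initial_speed = readr::col_double(),
    final_speed = readr::col_double()
  )
}

act_col_types <- function() {
  readr::cols(
    vehicle_id = readr::col_character(),
    start_time_utc = readr::col_character(),
    start_lat = readr::col_double(),
    start_lon = readr::col_double(),
    end_lat = readr::col_double(),
    end_lon = readr::col_double(),
    start_address = readr::col_character(),
    end_address = readr::col_character(),
    duration_s = readr::col_double(),
    distance = readr::col_double(),
    avg_speed = readr::col_double(),
    max_speed = readr::col_double(),
    n_sudden_accel = readr::col_integer(),
    n_hard_braking = readr::col_integer(),
    n_overspeeding = readr::col_integer(),
    overspeeding_duration_s = readr::col_double()
  )
}

# Accepts ISO-8601 strings or integer epoch seconds; returns POSIXct UTC.
parse_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    return(lubridate::with_tz(x, "UTC"))
  }
  x <- as.character(x)
  numeric_like <- grepl("^\\s*-?[0-9]+(\\.[0-9]+)?\\s*$", x) & !is.na(x)
  out <- rep(lubridate::as_datetime(NA), length(x))
  if (any(numeric_like)) {
    out[numeric_like] <- lubridate::as_datetime(as.numeric(x[numeric_like]), tz = "UTC")
  }
  if (any(!numeric_like)) {
    out[!numeric_like] <- lubridate::ymd_hms(x[!numeric_like], tz = "UTC", quiet = TRUE)
  }
  out
}

fmt_utc <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
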