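# builders for hand-sized inputs, and a cache of shared synthetic scenarios
# (generation is the expensive step; scenarios are deterministic in seed)

mk_bc <- function(veh = "1000000001", t = "2016-07-10 15:00:00", off_s = 0,
                  lat = 38.63, lon = -90.20, ev = "regular", speed = 30,
                  initial_speed = NA_real_, final_speed = NA_real_,
                  peak_speed = NA_real_, avg_event_speed = NA_real_) {
  n <- max(length(off_s), length(lat), length(lon), length(ev), length(speed))
  tibble::tibble(
    vehicle_id = rep_len(veh, n),
    timestamp_utc = lubridate::as_datetime(t, tz = "UTC") + rep_len(off_s, n),
    latitude = rep_len(lat, n), longitude = rep_len(lon, n),
    speed = rep_len(speed, n), odometer = NA_real_,
    event_type = rep_len(ev, n), nearest_address = NA_character_,
    peak_speed = rep_len(peak_speed, n),
    avg_event_speed = rep_len(avg_event_speed, n),
    initial_speed = rep_len(initial_speed, n),
    final_speed = rep_len(final_speed, n),
    source_file = "test", row_in_file = seq_len(n), event_known = TRUE
  )
}

mk_trip_crumbs <- function(veh = "1000000001", t0 = "2016-07-10 15:00:00",
                           n_regular = 3, lat0 = 38.63, lon0 = -90.20) {
  mk_bc(veh, t0, off_s = seq(0, by = 30, length.out = n_regular + 2),
        lat = lat0 + seq(0, by = 1e-4, length.out = n_regular + 2),
        lon = lon0,
        ev = c("ignition_on", rep("regular", n_regular), "ignition_off"),
        speed = c(0, rep(30, n_regular), 0))
}

mk_activity <- function(veh = "1000000001", t0 = "2016-07-10 15:00:00",
                        start_lat = 38.63, start_lon = -90.20,
                        end_lat = 38.64, end_lon = -90.21,
                        distance = 2.0, duration_s = 600,
                        n_hb = 0L, n_sa = 0L, n_os = 0L) {
  n <- max(length(t0), length(start_lat), length(end_lat), length(distance))
  tibble::tibble(
    vehicle_id = rep_len(veh, n),
    start_time_utc = lubridate::as_datetime(t0, tz = "UTC"),
    start_lat = rep_len(start_lat, n), start_lon = rep_len(start_lon, n),
    end_lat = rep_len(end_lat, n), end_lon = rep_len(end_lon, n),
    start_address = NA_character_, end_address = NA_character_,
    duration_s = rep_len(duration_s, n), distance = rep_len(distance, n),
    avg_speed = 25, max_speed = 40,
    n_sudden_accel = rep_len(as.integer(n_sa), n),
    n_hard_braking = rep_len(as.integer(n_hb), n),
    n_overspeeding = rep_len(as.integer(n_os), n),
    overspeeding_duration_s = 0,
    source_file = "test", row_in_file = seq_len(n)
  )
}

.scenario_cache <- new.env(parent = emptyenv())

cached_scenario <- function(key, config, seed) {
  if (!exists(key, envir = .scenario_cache)) {
    assign(key, drivecrumb::generate_scenario(config, seed), envir = .scenario_cache)
  }
  get(key, envir = .scenario_cache)
}

# a compact one-month scenario shared across ingest/trip/pipeline tests
small_scenario <- function() {
  cached_scenario(
    "small",
    drivecrumb::scenario_config(months = 1, trips_per_day = 1.5),
    seed = 7
  )
}

# one-month scenario with every corruption mode injected
corrupt_scenario <- function() {
  cached_scenario(
    "corrupt",
    drivecrumb::scenario_config(
      months = 1, trips_per_day = 3,
      corruption = list(n_zero_rows = 5, n_duplicates = 3, n_abandoned = 2,
                        n_na_ends = 2, n_zero_starts = 2, egypt_trip = TRUE,
                        defective_vehicle = TRUE)
    ),
    seed = 21
  )
}
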