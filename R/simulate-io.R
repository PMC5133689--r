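#' Write a scenario to disk in the ingest file layout
#'
#' Emits one breadcrumb CSV and one activity CSV per UTC day (the daily-feed
#' layout ingest expects), the road grid as GeoJSON, and the ground-truth
#' manifest as JSON. Every CSV starts with a `# seed:` comment line for
#' provenance (ingest skips `#` lines). Writing the same scenario twice
#' produces byte-identical files.
#'
#' @param scenario A `drivecrumb_scenario` from [generate_scenario()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list of the written breadcrumb and activity paths.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "drivecrumb_scenario"))
  dir.create(file.path(dir, "breadcrumbs"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "activity"), recursive = TRUE, showWarnings = FALSE)
  seed_line <- sprintf("# seed: %d", scenario$seed)

  crumbs <- scenario$crumbs %>%
    mutate(timestamp_utc = fmt_utc(.data$timestamp_utc)) %>%
    select(all_of(breadcrumb_cols()))
  days <- substr(crumbs$timestamp_utc, 1, 10)
  bc_paths <- purrr::imap_chr(split(crumbs, days), function(df, day) {
    p <- file.path(dir, "breadcrumbs", paste0("breadcrumbs_", gsub("-", "", day), ".csv"))
    writeLines(seed_line, p)
    readr::write_csv(df, p, append = TRUE, col_names = TRUE)
    p
  })

  act <- scenario$activity %>%
    mutate(start_time_utc = fmt_utc(.data$start_time_utc)) %>%
    select(all_of(activity_cols()))
  adays <- substr(act$start_time_utc, 1, 10)
  act_paths <- purrr::imap_chr(split(act, adays), function(df, day) {
    p <- file.path(dir, "activity", paste0("activity_", gsub("-", "", day), ".csv"))
    writeLines(seed_line, p)
    readr::write_csv(df, p, append = TRUE, col_names = TRUE)
    p
  })

  write_segments_geojson(scenario$segments, file.path(dir, "roads.geojson"),
                         scenario$config$center)
  manifest <- scenario$manifest
  manifest$trips <- as.data.frame(mutate(
    manifest$trips,
    start_time_utc = fmt_utc(.data$start_time_utc),
    end_time_utc = fmt_utc(.data$end_time_utc)
  ))
  manifest$sites <- as.data.frame(manifest$sites)
  manifest$anchors <- as.data.frame(manifest$anchors)
  manifest$destinations <- as.data.frame(manifest$destinations)
  if (nrow(manifest$alerts) > 0) {
    manifest$alerts <- as.data.frame(mutate(manifest$alerts,
                                            time_utc = fmt_utc(.data$time_utc)))
  } else {
    manifest$alerts <- data.frame()
  }
  manifest$expected$phase_counts <- as.data.frame(manifest$expected$phase_counts)
  manifest$expected$anchor_ignition_share <-
    as.list(manifest$expected$anchor_ignition_share)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(breadcrumbs = unname(bc_paths), activity = unname(act_paths)))
}

#' Generate a 1 Hz speed trace with injected events
#'
#' Baseline speed follows an AR(1) process around `base_speed` (small,
#' smooth second-to-second changes); injected hard-braking and
#' sudden-acceleration events apply a single one-second delta at or beyond
#' the respective threshold, followed by a gentle (at most 3 mph/s) return
#' to baseline so the injected delta is the only qualifying one. The trace
#' is clamped nonnegative.
#'
#' @param duration_s Trace length in seconds.
#' @param base_speed Baseline speed (mph).
#' @param events Tibble with `kind` (`"hard_braking"`/`"sudden_acceleration"`)
#'   and `t` (event second, `1 < t < duration_s - 10`); defaults to none.
#' @param braking_delta,accel_delta Magnitudes (mph in one second) applied
#'   for injected events (defaults 9 and 11).
#' @param ar_phi,ar_sd AR(1) parameters of the baseline noise.
#' @return Tibble `t`, `speed` (class `drivecrumb_speed_trace`) with the
#'   realized events as attribute `events`.
#' @export
generate_speed_trace <- function(duration_s, base_speed = 35, events = NULL,
                                 braking_delta = 9, accel_delta = 11,
                                 ar_phi = 0.8, ar_sd = 0.5) {
  n <- as.integer(duration_s)
  stopifnot(n >= 2)
  dev <- numeric(n)
  for (i in 2:n) {
    dev[i] <- ar_phi * dev[i - 1] + stats::rnorm(1, 0, ar_sd)
  }
  speed <- pmax(base_speed + dev, 0)
  if (!is.null(events) && nrow(events) > 0) {
    stopifnot(all(events$t > 1), all(events$t < n - 10))
    events <- arrange(events, .data$t)
    for (i in seq_len(nrow(events))) {
      te <- events$t[i]
      delta <- if (events$kind[i] == "hard_braking") -braking_delta else accel_delta
      target <- max(speed[te] + delta, 0)
      speed[te + 1] <- target
      # relax back toward baseline at <= 3 mph/s
      j <- te + 1
      while (j < n && abs(speed[j] - (base_speed + dev[j])) > 3) {
        step <- sign((base_speed + dev[j + 1]) - speed[j]) * 3
        speed[j + 1] <- speed[j] + step
        j <- j + 1
      }
    }
    speed <- pmax(speed, 0)
  }
  structure(tibble(t = seq_len(n), speed = speed),
            events = events, class = c("drivecrumb_speed_trace", "tbl_df", "tbl", "data.frame"))
}

#' Write the canonical mini-fixture suite
#'
#' Deterministic, hand-sized fixtures exercising one cleaning rule or spatial
#' metric each: a trip contaminated by a non-CONUS (Egypt-style) fix, exact
#' duplicate rows, an NA-trip-end activity file, a zero-start activity file,
#' and a two-anchor ignition-on constellation in which two clusters each
#' exceed the 10% primary-location share.
#'
#' @param out_dir Output directory.
#' @return Invisibly, the written file paths.
#' @export
write_fixture_suite <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)

  base_t <- lubridate::as_datetime("2016-07-10 15:00:00", tz = "UTC")
  mk_crumb <- function(t_off, lat, lon, ev, speed = 30) {
    tibble(
      vehicle_id = "1000000001", timestamp_utc = fmt_utc(base_t + t_off),
      latitude = lat, longitude = lon, speed = speed, odometer = NA_real_,
      event_type = ev, nearest_address = NA_character_, peak_speed = NA_real_,
      avg_event_speed = NA_real_, initial_speed = NA_real_, final_speed = NA_real_
    )
  }

  egypt <- bind_rows(
    mk_crumb(0, 38.6300, -90.2000, "ignition_on", 0),
    mk_crumb(30, 38.6310, -90.2005, "regular"),
    mk_crumb(60, 30.0400, 31.2400, "regular"),   # satellite-lock failure
    mk_crumb(90, 38.6330, -90.2015, "regular"),
    mk_crumb(120, 38.6340, -90.2020, "ignition_off", 0)
  )
  p <- file.path(out_dir, "breadcrumbs_egypt_trip.csv")
  readr::write_csv(egypt, p); paths <- c(paths, p)

  dup_src <- bind_rows(
    mk_crumb(0, 38.6300, -90.2000, "ignition_on", 0),
    mk_crumb(30, 38.6310, -90.2005, "regular"),
    mk_crumb(60, 38.6320, -90.2010, "regular"),
    mk_crumb(90, 38.6330, -90.2015, "ignition_off", 0)
  )
  dups <- bind_rows(dup_src[1:2, ], dup_src[2, ], dup_src[3:4, ])
  p <- file.path(out_dir, "breadcrumbs_exact_duplicate.csv")
  readr::write_csv(dups, p); paths <- c(paths, p)

  act <- tibble(
    vehicle_id = "1000000001",
    start_time_utc = fmt_utc(base_t + c(0, 3600, 7200)),
    start_lat = c(38.63, 38.63, 0), start_lon = c(-90.20, -90.20, 0),
    end_lat = c(38.64, NA, 38.64), end_lon = c(-90.21, NA, -90.21),
    start_address = NA_character_, end_address = NA_character_,
    duration_s = 600, distance = 2.5, avg_speed = 25, max_speed = 40,
    n_sudden_accel = 0L, n_hard_braking = 1L, n_overspeeding = 0L,
    overspeeding_duration_s = 0
  )
  p <- file.path(out_dir, "activity_na_end_zero_start.csv")
  readr::write_csv(act, p); paths <- c(paths, p)

  # two-anchor constellation: 6 and 3 ignition-ons (of 20 total) in tight
  # 20-ft clusters, the rest scattered singletons
  t_seq <- seq(0, by = 3600, length.out = 20)
  offs_a <- c(0, 2, -2, 1, -1, 0) * 1e-5       # ~ few feet
  offs_b <- c(0, 2, -2) * 1e-5
  two_anchor <- bind_rows(
    purrr::map2_dfr(t_seq[1:6], offs_a,
                    ~ mk_crumb(.x, 38.6300 + .y, -90.2000 + .y, "ignition_on", 0)),
    purrr::map2_dfr(t_seq[7:9], offs_b,
                    ~ mk_crumb(.x, 38.6500 + .y, -90.1800 + .y, "ignition_on", 0)),
    purrr::imap_dfr(t_seq[10:20],
                    ~ mk_crumb(.x, 38.60 + .y * 0.01, -90.25 + .y * 0.01,
                               "ignition_on", 0))
  )
  p <- file.path(out_dir, "breadcrumbs_two_anchor.csv")
  readr::write_csv(two_anchor, p); paths <- c(paths, p)

  invisible(paths)
}

#' Small valid breadcrumb rows for examples
#'
#' @param n Number of rows.
#' @return Tibble in the breadcrumb CSV schema (timestamps as ISO strings).
#' @export
synth_breadcrumb_rows <- function(n = 3) {
  t0 <- lubridate::as_datetime("2016-07-10 15:00:00", tz = "UTC")
  tibble(
    vehicle_id = "1000000001",
    timestamp_utc = fmt_utc(t0 + (seq_len(n) - 1) * 30),
    latitude = 38.63 + (seq_len(n) - 1) * 1e-4,
    longitude = -90.20 - (seq_len(n) - 1) * 1e-4,
    speed = 30, odometer = NA_real_,
    event_type = c("ignition_on", rep("regular", max(n - 1, 0))),
    nearest_address = NA_character_, peak_speed = NA_real_,
    avg_event_speed = NA_real_, initial_speed = NA_real_, final_speed = NA_real_
  )
}
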