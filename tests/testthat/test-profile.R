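mk_classified_trip <- function(veh = "1000000001", month = "2016-07", phase = "day",
                               t0 = "2016-07-10 18:00:00", id = "t1") {
  tibble::tibble(
    trip_id = id, vehicle_id = veh,
    start_time = lubridate::as_datetime(t0, tz = "UTC"),
    end_time = lubridate::as_datetime(t0, tz = "UTC") + 600,
    start_lat = 38.63, start_lon = -90.2, end_lat = 38.64, end_lon = -90.21,
    n_crumbs = 10L, abandoned = FALSE, complete = TRUE, usable = TRUE,
    crumbs = list(tibble::tibble()),
    tz_id = "America/Chicago", local_month = month, sun_phase = phase
  )
}

test_that("phase counts sum to totals and months with zero trips appear explicitly", {
  trips <- dplyr::bind_rows(
    mk_classified_trip(phase = "day", id = "a"),
    mk_classified_trip(phase = "dusk", id = "b"),
    mk_classified_trip(month = "2016-09", phase = "night", id = "c",
                       t0 = "2016-09-10 23:00:00")
  )
  counts <- count_trips_by_light(trips)
  expect_equal(nrow(counts), 3)   # July, August (gap), September
  aug <- counts[counts$local_month == "2016-08", ]
  expect_equal(aug$n_trips, 0L)
  expect_equal(counts$n_trips,
               counts$n_trips_day + counts$n_trips_dawn +
                 counts$n_trips_dusk + counts$n_trips_night)
  expect_equal(counts$n_trips_not_day,
               counts$n_trips - counts$n_trips_day)
})

test_that("per-driver totals and cohort mean/SD follow the summary-table definitions", {
  trips <- dplyr::bind_rows(
    mk_classified_trip(id = "a", t0 = "2016-07-10 18:00:00"),
    mk_classified_trip(id = "b", t0 = "2016-07-11 18:00:00")
  )
  act <- mk_activity(t0 = c("2016-07-10 18:00:00", "2016-07-11 18:00:00"),
                     distance = c(2, 4), duration_s = c(600, 1200),
                     n_hb = c(1L, 0L))
  st <- trip_statistics(trips, act)
  expect_equal(st$numtripsover5mo, 2L)
  expect_equal(st$tot_dist_driven5mo, 6)
  expect_equal(st$avg_trip_miles5mo, 3.0)
  expect_equal(st$trips_w_HB5mo, 1L)
  expect_equal(st$numofdays, 2L)
  expect_equal(st$tot_drv_hrs5mo, 0.5)

  # a cohort of identical drivers has zero SD; mean/SD match stats oracles
  cohort <- dplyr::bind_rows(st, dplyr::mutate(st, id = "v2"),
                             dplyr::mutate(st, id = "v3"))
  cs <- cohort_summary(cohort)
  expect_true(all(cs$sd == 0))
  varied <- dplyr::bind_rows(
    st, dplyr::mutate(st, id = "v2", numtripsover5mo = 10L),
    dplyr::mutate(st, id = "v3", numtripsover5mo = 20L)
  )
  cs2 <- cohort_summary(varied)
  trips_row <- cs2[cs2$metric == "numtripsover5mo", ]
  expect_equal(trips_row$mean, mean(c(2, 10, 20)))
  expect_equal(trips_row$sd, sd(c(2, 10, 20)))
})

test_that("assembled profiles are internally consistent and null-mark defective devices", {
  scn <- small_scenario()
  dir <- withr::local_tempdir()
  paths <- write_scenario(scn, dir)
  out <- run_pipeline(paths$breadcrumbs, paths$activity,
                      proj_center = scn$config$center)
  p <- out$profiles
  expect_s3_class(p, "drivecrumb_profile")
  expect_equal(p$n_trips,
               p$n_trips_day + p$n_trips_dawn + p$n_trips_dusk + p$n_trips_night)
  with_trips <- dplyr::filter(p, n_trips > 0)
  expect_equal(with_trips$mean_miles_per_trip,
               with_trips$total_miles / with_trips$n_trips)
  # monthly sums aggregate conservatively to window totals
  st <- trip_statistics(out$trips, out$activity)
  expect_equal(sum(p$n_trips), st$numtripsover5mo)
  expect_equal(sum(p$total_miles), st$tot_dist_driven5mo, tolerance = 1e-9)
  expect_equal(sum(p$n_trips_night), st$trips_at_night5mo)

  # identical months give zero month-over-month deltas
  two_same <- dplyr::bind_rows(
    dplyr::mutate(p[1, ], local_month = "2016-07"),
    dplyr::mutate(p[1, ], local_month = "2016-08")
  )
  expect_equal(diff(two_same$n_trips), 0L)

  # defective vehicles are explicitly null-marked
  p2 <- assemble_profile(out$trips, out$activity, out$crumbs,
                         defective_vehicles = unique(out$trips$vehicle_id))
  expect_true(all(p2$excluded_reason == "defective_device"))
  expect_true(all(is.na(p2$n_trips)))

  # tidy/glance interfaces
  expect_true(all(c("metric", "value") %in% names(tidy(p))))
  g <- glance(p)
  expect_equal(g$n_trips, sum(p$n_trips))
})
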