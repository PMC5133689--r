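test_that("coordinate filter removes zero/out-of-area fixes and contaminated trips", {
  crumbs <- dplyr::bind_rows(
    mk_trip_crumbs(t0 = "2016-07-10 15:00:00"),              # valid St. Louis trip
    mk_bc(off_s = 4000, lat = 0, lon = 0, ev = "device_connect"),
    mk_trip_crumbs(t0 = "2016-07-10 17:00:00")
  )
  # contaminate second trip with an Egypt fix
  i <- which(crumbs$timestamp_utc == lubridate::as_datetime("2016-07-10 17:00:30"))
  crumbs$latitude[i] <- 30.04
  crumbs$longitude[i] <- 31.24

  res <- filter_coordinates(crumbs)
  expect_equal(nrow(res$kept) + nrow(res$removed), nrow(crumbs))
  expect_equal(sum(res$removed$reason == "zero_coordinates"), 1)
  expect_equal(sum(res$removed$reason == "outside_bbox"), 1)
  # every crumb of the contaminated trip goes with it
  expect_equal(sum(res$removed$reason == "trip_contaminated"), 4)
  expect_equal(nrow(res$kept), 5)
  expect_true(all(res$kept$latitude > 24.5 & res$kept$latitude < 49.5))

  # idempotent
  res2 <- filter_coordinates(res$kept)
  expect_equal(nrow(res2$removed), 0)
  expect_equal(res2$kept$timestamp_utc, res$kept$timestamp_utc)
})

test_that("timestamp de-duplication keeps the first row and flags conflicts", {
  base <- mk_trip_crumbs()
  exact <- dplyr::bind_rows(base, base[2, ])
  res <- dedupe_timestamps(exact)
  expect_equal(nrow(res$kept), nrow(base))
  expect_equal(nrow(res$removed), 1)
  expect_false(res$removed$conflict[1])

  conflicting <- dplyr::bind_rows(base, dplyr::mutate(base[2, ], latitude = 40))
  res2 <- dedupe_timestamps(conflicting)
  expect_equal(nrow(res2$removed), 1)
  expect_true(res2$removed$conflict[1])
  expect_equal(res2$kept$latitude[2], base$latitude[2])  # first occurrence wins

  # same timestamp, different vehicles: both kept
  two_veh <- dplyr::bind_rows(base, dplyr::mutate(base, vehicle_id = "2000000002"))
  res3 <- dedupe_timestamps(two_veh)
  expect_equal(nrow(res3$removed), 0)

  # idempotent
  res4 <- dedupe_timestamps(res$kept)
  expect_equal(nrow(res4$removed), 0)
})

test_that("trip-record filter removes NA ends and zero starts with reasons", {
  act <- mk_activity(
    t0 = sprintf("2016-07-10 %02d:00:00", 10:13),
    end_lat = c(38.64, NA, 38.64, 38.64),
    start_lon = c(-90.2, -90.2, 0, -90.2)
  )
  res <- filter_trips(act)
  expect_equal(nrow(res$kept), 2)
  expect_setequal(res$removed$reason, c("na_end", "zero_start"))
  expect_true(all(is.finite(res$kept$end_lat) & res$kept$end_lat != 0))
  # idempotent and row-conserving
  expect_equal(nrow(filter_trips(res$kept)$removed), 0)
  expect_equal(nrow(res$kept) + nrow(res$removed), nrow(act))
})

test_that("defective-device flagging needs a sustained zero-coordinate window", {
  # two weeks of zeros at 3-hour cadence
  dead <- mk_bc(veh = "9999999999", off_s = seq(0, 14 * 86400, by = 3 * 3600),
                lat = 0, lon = 0)
  healthy <- mk_trip_crumbs(veh = "1000000001")
  one_zero <- dplyr::bind_rows(
    mk_trip_crumbs(veh = "3000000003"),
    mk_bc(veh = "3000000003", off_s = 7200, lat = 0, lon = 0,
          ev = "device_connect")
  )
  flagged <- flag_defective_devices(dplyr::bind_rows(dead, healthy, one_zero))
  expect_equal(flagged, "9999999999")
})

test_that("cleaning removes exactly the injected corruption and nothing else", {
  scn <- corrupt_scenario()
  man <- scn$manifest$corruption
  cl <- clean_driving_data(scn$crumbs, scn$activity)

  reasons <- cl$report$crumb_reason_counts
  n_reason <- function(r) {
    n <- reasons$n[reasons$reason == r]
    if (length(n) == 0) 0L else n
  }
  expect_equal(n_reason("zero_coordinates"),
               man$n_zero_rows + man$defective_vehicle_crumbs)
  expect_equal(n_reason("outside_bbox") + n_reason("trip_contaminated"),
               man$egypt_trip_crumbs)
  expect_equal(n_reason("duplicate_timestamp"), man$n_duplicates)

  treasons <- cl$report$trip_reason_counts
  expect_equal(treasons$n[treasons$reason == "na_end"],
               man$n_abandoned + man$n_na_ends)
  expect_equal(treasons$n[treasons$reason == "zero_start"], man$n_zero_starts)

  expect_equal(cl$report$defective_vehicle_ids, man$defective_vehicle_id)

  # nothing else: totals reconcile exactly
  expect_equal(nrow(cl$crumbs) + nrow(cl$removed_crumbs), nrow(scn$crumbs))
  expect_equal(nrow(cl$removed_crumbs),
               man$n_zero_rows + man$defective_vehicle_crumbs +
                 man$egypt_trip_crumbs + man$n_duplicates)
  expect_equal(nrow(cl$removed_trips),
               man$n_abandoned + man$n_na_ends + man$n_zero_starts)
})

test_that("commuting filters give the same kept set in either order", {
  scn <- corrupt_scenario()
  key <- function(df) paste(df$vehicle_id, format(df$timestamp_utc), df$latitude)
  a <- dedupe_timestamps(filter_coordinates(scn$crumbs)$kept)$kept
  b <- filter_coordinates(dedupe_timestamps(scn$crumbs)$kept)$kept
  expect_setequal(key(a), key(b))
})
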