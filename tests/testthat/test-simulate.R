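test_that("regeneration with the same seed emits byte-identical files", {
  cfg <- scenario_config(months = 1, trips_per_day = 1,
                         corruption = list(n_zero_rows = 2, n_duplicates = 1))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_scenario(generate_scenario(cfg, seed = 7), d1)
  write_scenario(generate_scenario(cfg, seed = 7), d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_equal(f1, f2)
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # a different seed changes the stream
  d3 <- withr::local_tempdir()
  write_scenario(generate_scenario(cfg, seed = 8), d3)
  csvs <- grep("breadcrumbs_.*csv", f1, value = TRUE)
  expect_false(identical(
    unlist(lapply(csvs, function(f) tryCatch(readLines(file.path(d1, f)),
                                             error = function(e) ""))),
    unlist(lapply(list.files(d3, recursive = TRUE, pattern = "breadcrumbs_.*csv"),
                  function(f) readLines(file.path(d3, f))))
  ))
})

test_that("infeasible configurations are rejected before generation", {
  expect_error(scenario_config(anchor_shares = c(0.7, 0.4)), "sum to < 1")
  expect_error(scenario_config(anchor_shares = numeric(0)), "one or two")
  expect_error(scenario_config(phase_probs = c(day = 0.5, dusk = 0.1,
                                               night = 0.1, dawn = 0.1)),
               "sum to 1")
  expect_error(scenario_config(months = 0), "schedule")
})

test_that("emitted ignition-on rows match the manifest shares and scale with config", {
  cfg <- scenario_config(months = 2, trips_per_day = 3.7,
                         anchor_shares = c(0.55, 0.25))
  scn <- cached_scenario("two_anchor_shares", cfg, seed = 5)
  crumbs <- project_local(scn$crumbs, center = cfg$center)
  ign <- dplyr::filter(crumbs, event_type == "ignition_on")
  n_tot <- nrow(scn$manifest$trips)
  expect_equal(nrow(ign), n_tot)   # one ignition-on per scheduled trip
  for (a in 1:2) {
    anchor <- scn$manifest$anchors[a, ]
    near <- sum(sqrt((ign$x - anchor$x)^2 + (ign$y - anchor$y)^2) < 50)
    # exact agreement with the manifest's realized share
    expect_equal(near / n_tot,
                 scn$manifest$expected$anchor_ignition_share[[paste0("anchor", a)]])
    # and statistical agreement with the configured share (binomial 3-sigma)
    p <- cfg$anchor_shares[a]
    expect_lt(abs(near / n_tot - p), 3 * sqrt(p * (1 - p) / n_tot))
  }
})

test_that("corruption injection emits exactly the configured counts", {
  scn <- corrupt_scenario()
  man <- scn$manifest$corruption
  expect_equal(man$n_zero_rows, 5L)
  expect_equal(man$n_duplicates, 3L)
  expect_equal(man$n_abandoned, 2L)
  expect_equal(man$n_na_ends, 2L)
  expect_equal(man$n_zero_starts, 2L)
  # the rows are really present in the emitted streams
  standalone_zero <- dplyr::filter(scn$crumbs, latitude == 0,
                                   vehicle_id == scn$config$vehicle_id,
                                   event_type == "device_connect")
  expect_equal(nrow(standalone_zero), 5)
  key <- paste(scn$crumbs$vehicle_id, scn$crumbs$timestamp_utc)
  expect_equal(sum(duplicated(key)), 3)
  expect_equal(sum(is.na(scn$activity$end_lat)), 4)  # 2 abandoned + 2 na_ends
  expect_equal(sum(scn$activity$start_lat == 0, na.rm = TRUE), 2)
  egypt <- dplyr::filter(scn$crumbs, longitude > 0)
  expect_equal(nrow(egypt), 1)
})

test_that("3-hour idle pings appear between trips and never inside them", {
  scn <- small_scenario()
  pings <- dplyr::filter(scn$crumbs, event_type == "idle_ping")
  expect_gt(nrow(pings), 0)
  trips <- scn$manifest$trips
  inside <- purrr::map_lgl(pings$timestamp_utc, function(t) {
    any(t >= trips$start_time_utc & t <= trips$end_time_utc)
  })
  expect_false(any(inside))
  # every ping sits a whole number of 3-hour intervals after the last trip end
  prev_end <- purrr::map_dbl(pings$timestamp_utc, function(t) {
    max(as.numeric(trips$end_time_utc)[as.numeric(trips$end_time_utc) < as.numeric(t)])
  })
  off <- as.numeric(pings$timestamp_utc) - prev_end
  expect_true(all(off %% (3 * 3600) == 0 & off > 0))
})
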