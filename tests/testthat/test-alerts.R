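test_that("device alerts reconcile with activity counts; orphans are kept and flagged", {
  trip <- mk_trip_crumbs(n_regular = 4)
  brake1 <- mk_bc(off_s = 45, ev = "hard_braking", speed = 30,
                  initial_speed = 30, final_speed = 20)
  brake2 <- mk_bc(off_s = 75, ev = "hard_braking", speed = 30,
                  initial_speed = 32, final_speed = 22)
  orphan <- mk_bc(off_s = 5000, ev = "sudden_acceleration", speed = 20,
                  initial_speed = 10, final_speed = 22)
  crumbs <- dplyr::bind_rows(trip, brake1, brake2, orphan)
  act <- mk_activity(n_hb = 2L)
  ev <- extract_alerts(crumbs, act)
  expect_equal(nrow(ev), 3)
  expect_equal(sum(ev$kind == "hard_braking"), 2)
  expect_equal(sum(ev$orphan), 1)
  expect_true(all(ev$source == "device_reported"))
  expect_true(is.null(attr(ev, "discrepancies")) ||
                nrow(attr(ev, "discrepancies")) == 0)

  # a mismatching activity count is reported as a discrepancy
  act_bad <- mk_activity(n_hb = 3L)
  ev2 <- suppressMessages(extract_alerts(crumbs, act_bad))
  expect_equal(nrow(attr(ev2, "discrepancies")), 1)
})

test_that("overspeeding recomputation: maximal runs at margin over the limit proxy", {
  mk_annotated <- function(speeds) {
    n <- length(speeds)
    dplyr::mutate(
      mk_bc(off_s = seq(0, by = 30, length.out = n), ev = "regular",
            speed = speeds),
      trip_id = "t1", road_avg_speed = 35
    )
  }
  # constant limit + 5: never an event
  expect_equal(nrow(recompute_overspeeding(mk_annotated(rep(40, 6)))), 0)
  # a bounded run of 3 crumbs at limit + 10: one event with that peak
  ev <- recompute_overspeeding(mk_annotated(c(35, 36, 45, 45, 45, 36)))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_crumbs, 3L)
  expect_equal(ev$peak_speed, 45)
  # two separated runs: two events; boundary crumb at exactly limit+6 counts
  ev2 <- recompute_overspeeding(mk_annotated(c(41, 35, 41, 35)))
  expect_equal(nrow(ev2), 2)
})

test_that("1 Hz braking/acceleration detection honours the 8/10 mph-per-second pair", {
  smooth <- tibble::tibble(t = 1:60, speed = 30 + 3 * sin((1:60) / 5))
  expect_equal(nrow(recompute_accel_events(smooth)), 0)

  drop9 <- tibble::tibble(t = 1:20, speed = c(rep(30, 10), 21, rep(21, 9)))
  ev <- recompute_accel_events(drop9)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "hard_braking")
  expect_equal(ev$initial_speed, 30)
  expect_equal(ev$final_speed, 21)

  # an 8-mph rise is not sudden acceleration (threshold 10), a 9-mph drop is braking
  rise8 <- tibble::tibble(t = 1:20, speed = c(rep(20, 10), 28, rep(28, 9)))
  expect_equal(nrow(recompute_accel_events(rise8)), 0)
  # consecutive qualifying seconds merge into one event
  double_drop <- tibble::tibble(t = 1:20, speed = c(rep(40, 8), 31, 22, rep(22, 10)))
  ev2 <- recompute_accel_events(double_drop)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$initial_speed, 40)
  expect_equal(ev2$final_speed, 22)
})

test_that("speed traces with injected events are recovered exactly", {
  set.seed(41)
  for (rep in 1:10) {
    n_ev <- sample(0:3, 1)
    ts <- sort(sample(seq(10, 260, by = 20), n_ev))
    kinds <- sample(c("hard_braking", "sudden_acceleration"), n_ev, replace = TRUE)
    events <- tibble::tibble(kind = kinds, t = ts)
    trace <- generate_speed_trace(300, base_speed = 40, events = events)
    got <- recompute_accel_events(trace)
    expect_equal(nrow(got), n_ev)
    if (n_ev > 0) {
      expect_equal(got$kind, kinds)
      expect_equal(got$t_start, ts, tolerance = 1.01)   # within one second
    }
  }
})

test_that("recomputed and device-reported overspeeding agree on a uniform-limit world", {
  cfg <- scenario_config(months = 1, trips_per_day = 2,
                         grid_speeds = c(35, 35, 35),
                         alert_rates = c(hard_braking = 0.1,
                                         sudden_acceleration = 0.1,
                                         overspeeding = 0.3))
  scn <- cached_scenario("uniform", cfg, seed = 31)
  crumbs <- project_local(assign_trip_ids(scn$crumbs), center = scn$config$center)
  crumbs <- annotate_breadcrumbs(crumbs, scn$segments)
  rec <- recompute_overspeeding(crumbs)
  dev <- dplyr::filter(scn$crumbs, event_type == "overspeeding")
  expect_equal(nrow(rec), nrow(dev))
  expect_equal(nrow(rec), sum(scn$manifest$trips$n_os))
})
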