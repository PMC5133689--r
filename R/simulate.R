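#' Build a synthetic planar road grid
#'
#' A square grid of street centerlines (default spacing 500 m) with speed
#' classes 25/35/55 mph mapped to CFCC-like codes (A41 local, A31 secondary,
#' A21 primary): the simplest road world that exercises nearest-segment
#' matching and the overspeeding definition. Each block edge is one segment;
#' coordinates are metres in the scenario frame centred on the grid.
#'
#' @param n Nodes per side (default 15).
#' @param spacing_m Node spacing (default 500).
#' @param speeds Length-3 numeric: local/secondary/primary class speeds in
#'   mph (default `c(25, 35, 55)`); pass equal values for a uniform-limit
#'   world.
#' @return Segment tibble for [build_segment_index()], with attribute `nodes`
#'   (tibble of node `i`, `j`, `x`, `y`).
#' @export
make_road_grid <- function(n = 15, spacing_m = 500, speeds = c(25, 35, 55)) {
  stopifnot(n >= 2, length(speeds) == 3)
  coord <- (seq_len(n) - (n + 1) / 2) * spacing_m
  line_class <- function(idx) {
    if (idx %% 5 == 0) c(speeds[3], "A21")
    else if (idx %% 2 == 0) c(speeds[2], "A31")
    else c(speeds[1], "A41")
  }
  segs <- list()
  sid <- 0L
  for (j in seq_len(n)) {          # east-west streets (constant y)
    cl <- line_class(j)
    for (i in seq_len(n - 1)) {
      sid <- sid + 1L
      segs[[sid]] <- tibble(
        segment_id = sid, name = sprintf("EW-%02d St", j), cfcc = cl[2],
        avg_speed = as.numeric(cl[1]),
        polyline = list(cbind(c(coord[i], coord[i + 1]), c(coord[j], coord[j])))
      )
    }
  }
  for (i in seq_len(n)) {          # north-south avenues (constant x)
    cl <- line_class(i + 1)        # offset so rows/cols differ
    for (j in seq_len(n - 1)) {
      sid <- sid + 1L
      segs[[sid]] <- tibble(
        segment_id = sid, name = sprintf("NS-%02d Ave", i), cfcc = cl[2],
        avg_speed = as.numeric(cl[1]),
        polyline = list(cbind(c(coord[i], coord[i]), c(coord[j], coord[j + 1])))
      )
    }
  }
  out <- bind_rows(segs)
  nodes <- tidyr::expand_grid(i = seq_len(n), j = seq_len(n)) %>%
    mutate(x = coord[.data$i], y = coord[.data$j])
  attr(out, "nodes") <- nodes
  out
}

#' Scenario configuration for the synthetic driver simulator
#'
#' Defaults encode the emulated study conditions: five months starting
#' 2016-07-01, one driver, about 3.7 trips per day, 30-second breadcrumbs,
#' 3-hour idle pings, GPS noise of 5 ft parked / 15 ft moving, a day-dominant
#' phase mix with more dusk than dawn departures, and a 15 x 15 grid world at
#' 500 m spacing centred on St. Louis.
#'
#' @param months Number of calendar months.
#' @param start_date First local date (`"YYYY-MM-DD"`).
#' @param vehicle_id 10-digit device code.
#' @param center `c(lat, lon)` of the road-world centre.
#' @param tz IANA zone of the world.
#' @param grid_n,grid_spacing_m Road-grid shape.
#' @param grid_speeds Speed classes passed to [make_road_grid()].
#' @param anchor_shares Per-anchor probability that a trip starts there
#'   (one or two anchors); the remainder starts at ordinary destinations.
#'   Must sum to less than 1.
#' @param n_destinations Number of ordinary destination sites.
#' @param trips_per_day Poisson mean of daily trips.
#' @param phase_probs Named day/dusk/night/dawn departure probabilities.
#' @param noise_parked_ft,noise_moving_ft Isotropic GPS noise sd (feet).
#' @param sampling_interval_s Breadcrumb interval (30 s).
#' @param idle_ping_interval_h Parked ping interval (3 h).
#' @param alert_rates Named per-trip Poisson means for `hard_braking`,
#'   `sudden_acceleration`, `overspeeding` injections.
#' @param overspeed_margin_mph Margin used when elevating crumbs for injected
#'   overspeeding (crumbs are set to limit + margin + 4).
#' @param corruption List of corruption counts/switches: `n_zero_rows`,
#'   `n_duplicates`, `n_abandoned`, `n_na_ends`, `n_zero_starts`,
#'   `egypt_trip`, `defective_vehicle`.
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(months = 5, start_date = "2016-07-01",
                            vehicle_id = "1000000001",
                            center = c(38.63, -90.20), tz = "America/Chicago",
                            grid_n = 15, grid_spacing_m = 500,
                            grid_speeds = c(25, 35, 55),
                            anchor_shares = 0.5, n_destinations = 8,
                            trips_per_day = 3.7,
                            phase_probs = c(day = 0.82, dusk = 0.09,
                                            night = 0.07, dawn = 0.02),
                            noise_parked_ft = 5, noise_moving_ft = 15,
                            sampling_interval_s = 30, idle_ping_interval_h = 3,
                            alert_rates = c(hard_braking = 0.15,
                                            sudden_acceleration = 0.08,
                                            overspeeding = 0.12),
                            overspeed_margin_mph = 6,
                            corruption = list()) {
  cfg <- list(
    months = months, start_date = start_date, vehicle_id = vehicle_id,
    center = center, tz = tz, grid_n = grid_n, grid_spacing_m = grid_spacing_m,
    grid_speeds = grid_speeds,
    anchor_shares = anchor_shares, n_destinations = n_destinations,
    trips_per_day = trips_per_day, phase_probs = phase_probs,
    noise_parked_ft = noise_parked_ft, noise_moving_ft = noise_moving_ft,
    sampling_interval_s = sampling_interval_s,
    idle_ping_interval_h = idle_ping_interval_h,
    alert_rates = alert_rates, overspeed_margin_mph = overspeed_margin_mph,
    corruption = utils::modifyList(
      list(n_zero_rows = 0, n_duplicates = 0, n_abandoned = 0, n_na_ends = 0,
           n_zero_starts = 0, egypt_trip = FALSE, defective_vehicle = FALSE),
      corruption
    )
  )
  validate_scenario_config(cfg)
  structure(cfg, class = "scenario_config")
}

validate_scenario_config <- function(cfg) {
  if (sum(cfg$anchor_shares) >= 1) {
    abort("infeasible config: anchor shares must sum to < 1")
  }
  if (length(cfg$anchor_shares) < 1 || length(cfg$anchor_shares) > 2) {
    abort("one or two anchors are supported")
  }
  if (any(cfg$anchor_shares <= 0)) abort("anchor shares must be positive")
  if (abs(sum(cfg$phase_probs) - 1) > 1e-6) abort("phase_probs must sum to 1")
  if (cfg$months < 1 || cfg$trips_per_day <= 0) abort("infeasible schedule config")
  invisible(cfg)
}

#' Generate a ground-truthed synthetic driving scenario
#'
#' Emits a full breadcrumb and activity stream for one driver over the
#' configured window — 30-second fixes along grid routes with Gaussian GPS
#' noise, ignition on/off brackets, 3-hour idle pings while parked, injected
#' adverse-driving alerts, and the configured corruption modes — together
#' with the ground-truth manifest every pipeline stage can be checked
#' against. Regeneration with the same config and seed is deterministic.
#'
#' @param config A [scenario_config()].
#' @param seed Integer RNG seed.
#' @return List of class `drivecrumb_scenario`: `crumbs`, `activity`
#'   (tibbles in the ingest schema with parsed timestamps), `segments`,
#'   `manifest` (anchors, destinations, trips, alerts, corruption log,
#'   expected clean-pipeline outcomes), `config`, `seed`.
#' @export
generate_scenario <- function(config = scenario_config(), seed = 1) {
  stopifnot(inherits(config, "scenario_config"))
  validate_scenario_config(config)
  with_local_seed(seed, generate_scenario_impl(config, seed))
}

with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

generate_scenario_impl <- function(cfg, seed) {
  segments <- make_road_grid(cfg$grid_n, cfg$grid_spacing_m, cfg$grid_speeds)
  nodes <- attr(segments, "nodes")
  n <- cfg$grid_n

  # sites: anchors then destinations, on distinct interior nodes
  interior <- filter(nodes, .data$i > 1, .data$i < n, .data$j > 1, .data$j < n)
  n_anchor <- length(cfg$anchor_shares)
  picks <- interior[sample.int(nrow(interior), n_anchor + cfg$n_destinations), ]
  sites <- picks %>%
    mutate(
      site_id = c(paste0("anchor", seq_len(n_anchor)),
                  paste0("dest", seq_len(cfg$n_destinations))),
      is_anchor = c(rep(TRUE, n_anchor), rep(FALSE, cfg$n_destinations)),
      share = c(cfg$anchor_shares, rep(NA_real_, cfg$n_destinations))
    )
  ll <- unproject_local(sites$x, sites$y, cfg$center)
  sites$latitude <- ll$latitude
  sites$longitude <- ll$longitude

  # local-calendar day sequence and per-day solar windows
  d0 <- lubridate::ymd(cfg$start_date)
  d1 <- lubridate::add_with_rollback(d0, lubridate::period(months = cfg$months)) - 1
  days <- seq(d0, d1, by = "day")
  solar <- solar_day(cfg$center[1], cfg$center[2], days, tz = cfg$tz)

  sched <- build_schedule(cfg, sites, days, solar)
  streams <- emit_trips(cfg, sites, sched, segments)
  crumbs <- streams$crumbs
  activity <- streams$activity

  pings <- emit_idle_pings(cfg, streams$trips, sites)
  crumbs <- bind_rows(crumbs, pings)

  corr <- inject_corruption(cfg, crumbs, activity, streams$trips, sites)
  crumbs <- corr$crumbs
  activity <- corr$activity
  trips_manifest <- corr$trips

  crumbs <- arrange(crumbs, .data$vehicle_id, .data$timestamp_utc,
                    .data$emit_order)
  activity <- arrange(activity, .data$vehicle_id, .data$start_time_utc)

  clean_trips <- filter(trips_manifest, !.data$corrupted)
  phase_counts <- clean_trips %>%
    mutate(local_month = format(lubridate::with_tz(.data$start_time_utc, cfg$tz), "%Y-%m")) %>%
    count(.data$local_month, .data$phase)
  manifest <- list(
    seed = seed,
    sites = sites,
    anchors = filter(sites, .data$is_anchor),
    destinations = filter(sites, !.data$is_anchor),
    trips = trips_manifest,
    alerts = streams$alerts,
    corruption = corr$log,
    expected = list(
      n_trips_clean = nrow(clean_trips),
      phase_counts = phase_counts,
      alert_counts = c(
        hard_braking = sum(clean_trips$n_hb),
        sudden_acceleration = sum(clean_trips$n_sa),
        overspeeding = sum(clean_trips$n_os)
      ),
      anchor_ignition_share = {
        tot <- nrow(trips_manifest)
        vapply(paste0("anchor", seq_len(n_anchor)),
               function(a) sum(trips_manifest$origin == a) / tot, 0)
      }
    )
  )
  structure(
    list(crumbs = select(crumbs, -"emit_order"), activity = activity,
         segments = segments, manifest = manifest, config = cfg, seed = seed),
    class = "drivecrumb_scenario"
  )
}

# sample trip start times by phase inside that day's solar windows
build_schedule <- function(cfg, sites, days, solar) {
  out <- list()
  k <- 0L
  prev_end <- lubridate::as_datetime("1900-01-01", tz = "UTC")
  site_ids <- sites$site_id
  anchor_ids <- site_ids[sites$is_anchor]
  dest_ids <- site_ids[!sites$is_anchor]
  p_anchor <- cfg$anchor_shares
  for (di in seq_along(days)) {
    n_t <- stats::rpois(1, cfg$trips_per_day)
    if (n_t == 0) next
    phases <- sample(names(cfg$phase_probs), n_t, replace = TRUE,
                     prob = cfg$phase_probs)
    starts <- purrr::map_vec(phases, ~ sample_phase_instant(.x, solar[di, ]))
    ord <- order(starts)
    starts <- starts[ord]
    phases <- phases[ord]
    for (ti in seq_len(n_t)) {
      if (is.na(starts[ti])) next
      u <- stats::runif(1)
      origin <- if (u < sum(p_anchor)) {
        anchor_ids[1 + (u >= p_anchor[1])]
      } else {
        sample(dest_ids, 1)
      }
      dest <- sample(setdiff(site_ids, origin), 1)
      k <- k + 1L
      out[[k]] <- tibble(
        trip_idx = k, date = days[di],
        start_time_utc = starts[ti],
        phase = phases[ti], origin = origin, dest = dest
      )
    }
  }
  sched <- bind_rows(out)
  # enforce chronological non-overlap downstream (emit_trips drops clashes)
  arrange(sched, .data$start_time_utc)
}

sample_phase_instant <- function(phase, sol) {
  # interior margins keep scheduled instants robust to the small solar-time
  # shift between the world centre and the actual origin site
  margin <- 300
  window <- switch(phase,
    day = c(sol$sunrise + margin, sol$sunset - margin),
    dawn = c(sol$civil_dawn + 90, sol$sunrise - 90),
    dusk = c(sol$sunset + 90, sol$civil_dusk - 90),
    night = {
      # evening-biased night departures (dusk > dawn in departure counts)
      if (stats::runif(1) < 0.75) {
        c(sol$civil_dusk + margin, sol$civil_dusk + margin + 3 * 3600)
      } else {
        c(sol$civil_dawn - 3 * 3600, sol$civil_dawn - margin)
      }
    }
  )
  if (any(is.na(window)) || window[2] <= window[1]) return(lubridate::as_datetime(NA))
  t <- window[1] + stats::runif(1) * as.numeric(difftime(window[2], window[1], units = "secs"))
  lubridate::as_datetime(round(as.numeric(t)), tz = "UTC")
}

mph_to_mps <- function(v) v * 1609.344 / 3600

# L-shaped route between grid sites: east-west along the origin's street,
# then north-south along the destination's avenue
build_route <- function(origin, dest, segments) {
  legs <- list()
  if (origin$x != dest$x) {
    legs[[length(legs) + 1]] <- list(
      from = c(origin$x, origin$y), to = c(dest$x, origin$y),
      speed = street_speed(segments, y = origin$y)
    )
  }
  if (origin$y != dest$y) {
    legs[[length(legs) + 1]] <- list(
      from = c(dest$x, origin$y), to = c(dest$x, dest$y),
      speed = avenue_speed(segments, x = dest$x)
    )
  }
  legs
}

street_speed <- function(segments, y) {
  hit <- purrr::detect_index(segments$polyline, ~ .x[1, 2] == y && .x[2, 2] == y)
  segments$avg_speed[hit]
}

avenue_speed <- function(segments, x) {
  hit <- purrr::detect_index(segments$polyline, ~ .x[1, 1] == x && .x[2, 1] == x)
  segments$avg_speed[hit]
}

route_position <- function(legs, dist) {
  remaining <- dist
  for (leg in legs) {
    len <- sqrt(sum((leg$to - leg$from)^2))
    if (remaining <= len) {
      f <- if (len == 0) 0 else remaining / len
      return(list(pos = leg$from + f * (leg$to - leg$from), speed = leg$speed))
    }
    remaining <- remaining - len
  }
  last <- legs[[length(legs)]]
  list(pos = last$to, speed = last$speed)
}

emit_trips <- function(cfg, sites, sched, segments) {
  dt <- cfg$sampling_interval_s
  site_row <- function(id) sites[sites$site_id == id, ]
  crumb_rows <- list()
  act_rows <- list()
  trip_rows <- list()
  alert_rows <- list()
  prev_end <- NULL
  kept <- 0L
  for (i in seq_len(nrow(sched))) {
    s <- sched[i, ]
    o <- site_row(s$origin); d <- site_row(s$dest)
    legs <- build_route(o, d, segments)
    if (length(legs) == 0) next
    lens <- vapply(legs, function(l) sqrt(sum((l$to - l$from)^2)), 0)
    total_len <- sum(lens)
    travel_s <- sum(lens / mph_to_mps(vapply(legs, `[[`, 0, "speed")))
    t0 <- s$start_time_utc
    t_end <- t0 + ceiling(travel_s)
    if (!is.null(prev_end) && t0 < prev_end + 120) next  # drop clashing trip
    prev_end <- t_end
    kept <- kept + 1L

    times <- if (floor(travel_s) >= dt) seq(dt, floor(travel_s), by = dt) else numeric(0)
    dists <- purrr::map(times, function(tt) {
      covered <- travelled_distance(legs, lens, tt)
      route_position(legs, covered)
    })
    limit <- vapply(dists, function(z) z$speed, 0)
    speed <- pmin(limit + stats::rnorm(length(limit), 0, 1.5), limit + 4)
    speed <- pmax(speed, 0)
    pos <- if (length(times) > 0) {
      matrix(unlist(purrr::map(dists, "pos")), ncol = 2, byrow = TRUE)
    } else {
      matrix(numeric(0), ncol = 2)
    }

    # injected overspeeding: elevate pairs of consecutive crumbs
    n_os <- stats::rpois(1, cfg$alert_rates[["overspeeding"]])
    os_starts <- pick_spaced(length(times) - 1, n_os, gap = 3)
    n_os <- length(os_starts)
    for (k in os_starts) {
      speed[k:(k + 1)] <- limit[k:(k + 1)] + cfg$overspeed_margin_mph + 4
    }

    noise_m <- cfg$noise_moving_ft * M_PER_FT
    park_m <- cfg$noise_parked_ft * M_PER_FT
    n_mid <- length(times)
    mid_x <- if (n_mid > 0) pos[, 1] + stats::rnorm(n_mid, 0, noise_m) else numeric(0)
    mid_y <- if (n_mid > 0) pos[, 2] + stats::rnorm(n_mid, 0, noise_m) else numeric(0)
    xs <- c(o$x + stats::rnorm(1, 0, park_m), mid_x,
            d$x + stats::rnorm(1, 0, park_m))
    ys <- c(o$y + stats::rnorm(1, 0, park_m), mid_y,
            d$y + stats::rnorm(1, 0, park_m))
    tt <- c(t0, t0 + times, t_end)
    ev <- c("ignition_on", rep("regular", n_mid), "ignition_off")
    sp <- c(0, speed, 0)
    ll <- unproject_local(xs, ys, cfg$center)
    trip_crumbs <- tibble(
      vehicle_id = cfg$vehicle_id, timestamp_utc = tt,
      latitude = ll$latitude, longitude = ll$longitude,
      speed = round(sp, 1), odometer = NA_real_, event_type = ev,
      nearest_address = NA_character_, peak_speed = NA_real_,
      avg_event_speed = NA_real_, initial_speed = NA_real_,
      final_speed = NA_real_, trip_idx = s$trip_idx
    )

    # overspeeding event rows (device channel), between the elevated pair
    for (k in os_starts) {
      pk <- limit[k] + cfg$overspeed_margin_mph + 4
      alert_rows[[length(alert_rows) + 1]] <- tibble(
        trip_idx = s$trip_idx, kind = "overspeeding",
        time_utc = t0 + times[k] + 1
      )
      trip_crumbs <- bind_rows(trip_crumbs, tibble(
        vehicle_id = cfg$vehicle_id, timestamp_utc = t0 + times[k] + 1,
        latitude = ll$latitude[k + 1], longitude = ll$longitude[k + 1],
        speed = round(pk, 1), odometer = NA_real_, event_type = "overspeeding",
        nearest_address = NA_character_, peak_speed = round(pk, 1),
        avg_event_speed = round(pk - 1, 1), initial_speed = NA_real_,
        final_speed = NA_real_, trip_idx = s$trip_idx
      ))
    }

    # braking / acceleration device events at distinct mid-trip instants,
    # strictly inside the ignition window
    n_hb <- stats::rpois(1, cfg$alert_rates[["hard_braking"]])
    n_sa <- stats::rpois(1, cfg$alert_rates[["sudden_acceleration"]])
    eligible <- which(times + 7 < travel_s)
    m <- min(n_hb + n_sa, length(eligible))
    slots <- eligible[sample.int(length(eligible), m)]
    kinds <- head(c(rep("hard_braking", n_hb), rep("sudden_acceleration", n_sa)), m)
    n_hb <- sum(kinds == "hard_braking")
    n_sa <- sum(kinds == "sudden_acceleration")
    for (z in seq_along(kinds)) {
      kind <- kinds[z]
      k <- slots[z]
      base_sp <- limit[k]
      t_ev <- t0 + times[k] + 7
      if (kind == "hard_braking") {
        ini <- base_sp; fin <- max(base_sp - 9, 0)
      } else {
        ini <- base_sp; fin <- base_sp + 11
      }
      alert_rows[[length(alert_rows) + 1]] <- tibble(
        trip_idx = s$trip_idx, kind = kind, time_utc = t_ev
      )
      trip_crumbs <- bind_rows(trip_crumbs, tibble(
        vehicle_id = cfg$vehicle_id, timestamp_utc = t_ev,
        latitude = ll$latitude[k + 1], longitude = ll$longitude[k + 1],
        speed = round(base_sp, 1), odometer = NA_real_, event_type = kind,
        nearest_address = NA_character_, peak_speed = NA_real_,
        avg_event_speed = NA_real_, initial_speed = round(ini, 1),
        final_speed = round(fin, 1), trip_idx = s$trip_idx
      ))
    }

    crumb_rows[[kept]] <- trip_crumbs
    km <- round(total_len / 1000, 1)
    act_rows[[kept]] <- tibble(
      vehicle_id = cfg$vehicle_id, start_time_utc = t0,
      start_lat = ll$latitude[1], start_lon = ll$longitude[1],
      end_lat = ll$latitude[length(xs)], end_lon = ll$longitude[length(xs)],
      start_address = paste0("site ", s$origin),
      end_address = paste0("site ", s$dest),
      duration_s = as.numeric(t_end - t0, units = "secs"),
      distance = km * MI_PER_KM,
      avg_speed = if (any(sp > 0)) round(mean(sp[sp > 0]), 1) else 0,
      max_speed = round(max(sp), 1),
      n_sudden_accel = n_sa, n_hard_braking = n_hb, n_overspeeding = n_os,
      overspeeding_duration_s = n_os * cfg$sampling_interval_s
    )
    trip_rows[[kept]] <- tibble(
      trip_idx = s$trip_idx, vehicle_id = cfg$vehicle_id,
      start_time_utc = t0, end_time_utc = t_end,
      phase = s$phase, origin = s$origin, dest = s$dest,
      route_len_m = total_len, n_crumbs = nrow(trip_crumbs),
      n_hb = n_hb, n_sa = n_sa, n_os = n_os, corrupted = FALSE
    )
  }
  crumbs <- bind_rows(crumb_rows) %>% mutate(emit_order = row_number())
  list(
    crumbs = crumbs,
    activity = bind_rows(act_rows),
    trips = bind_rows(trip_rows),
    alerts = bind_rows(alert_rows)
  )
}

travelled_distance <- function(legs, lens, tt) {
  remaining <- tt
  covered <- 0
  for (li in seq_along(legs)) {
    v <- mph_to_mps(legs[[li]]$speed)
    leg_t <- lens[li] / v
    if (remaining <= leg_t) return(covered + remaining * v)
    covered <- covered + lens[li]
    remaining <- remaining - leg_t
  }
  covered
}

pick_spaced <- function(n_slots, k, gap = 3) {
  if (n_slots < 1 || k < 1) return(integer(0))
  avail <- seq_len(n_slots)
  picks <- integer(0)
  for (z in seq_len(k)) {
    if (length(avail) == 0) break
    p <- if (length(avail) == 1) avail else sample(avail, 1)
    picks <- c(picks, p)
    avail <- setdiff(avail, (p - gap):(p + gap))
  }
  sort(picks)
}

emit_idle_pings <- function(cfg, trips, sites) {
  if (nrow(trips) < 2) return(empty_sim_crumbs())
  ping_gap <- cfg$idle_ping_interval_h * 3600
  park_m <- cfg$noise_parked_ft * M_PER_FT
  rows <- list()
  for (i in seq_len(nrow(trips) - 1)) {
    t_from <- trips$end_time_utc[i] + ping_gap
    t_to <- trips$start_time_utc[i + 1] - 60
    if (t_from > t_to) next
    times <- seq(t_from, t_to, by = ping_gap)
    site <- sites[sites$site_id == trips$dest[i], ]
    ll <- unproject_local(site$x + stats::rnorm(length(times), 0, park_m),
                          site$y + stats::rnorm(length(times), 0, park_m),
                          cfg$center)
    rows[[length(rows) + 1]] <- tibble(
      vehicle_id = cfg$vehicle_id, timestamp_utc = times,
      latitude = ll$latitude, longitude = ll$longitude,
      speed = 0, odometer = NA_real_, event_type = "idle_ping",
      nearest_address = NA_character_, peak_speed = NA_real_,
      avg_event_speed = NA_real_, initial_speed = NA_real_,
      final_speed = NA_real_, trip_idx = NA_integer_
    )
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) return(empty_sim_crumbs())
  mutate(out, emit_order = 1e6 + row_number())
}

empty_sim_crumbs <- function() {
  tibble(
    vehicle_id = character(), timestamp_utc = lubridate::as_datetime(character()),
    latitude = double(), longitude = double(), speed = double(),
    odometer = double(), event_type = character(), nearest_address = character(),
    peak_speed = double(), avg_event_speed = double(), initial_speed = double(),
    final_speed = double(), trip_idx = integer(), emit_order = double()
  )
}

inject_corruption <- function(cfg, crumbs, activity, trips, sites) {
  cr <- cfg$corruption
  log <- list()
  next_order <- max(crumbs$emit_order) + 1

  # standalone zero-coordinate device glitches between trips
  if (cr$n_zero_rows > 0) {
    gaps <- trip_gaps(trips)
    times <- avoid_timestamp_collisions(
      sample_gap_times(gaps, cr$n_zero_rows), crumbs$timestamp_utc
    )
    zero_rows <- tibble(
      vehicle_id = cfg$vehicle_id, timestamp_utc = times,
      latitude = 0, longitude = 0, speed = 0, odometer = NA_real_,
      event_type = "device_connect", nearest_address = NA_character_,
      peak_speed = NA_real_, avg_event_speed = NA_real_,
      initial_speed = NA_real_, final_speed = NA_real_,
      trip_idx = NA_integer_, emit_order = next_order + seq_along(times)
    )
    next_order <- next_order + length(times) + 1
    crumbs <- bind_rows(crumbs, zero_rows)
    log$n_zero_rows <- length(times)
  } else {
    log$n_zero_rows <- 0L
  }

  # one trip contaminated with a non-CONUS fix (satellite-lock failure)
  log$egypt_trip_idx <- NA_integer_
  log$egypt_trip_crumbs <- 0L
  if (isTRUE(cr$egypt_trip) && nrow(trips) > 0) {
    victims <- trips$trip_idx[!trips$corrupted]
    victim <- victims[ceiling(length(victims) / 2)]
    rows <- which(crumbs$trip_idx %in% victim & crumbs$event_type == "regular")
    if (length(rows) > 0) {
      r <- rows[1]
      crumbs$latitude[r] <- 30.04
      crumbs$longitude[r] <- 31.24
      trips$corrupted[trips$trip_idx == victim] <- TRUE
      log$egypt_trip_idx <- victim
      log$egypt_trip_crumbs <- sum(crumbs$trip_idx %in% victim)
    }
  }

  # exact duplicate rows (device retransmission)
  if (cr$n_duplicates > 0) {
    ok <- which(!is.na(crumbs$trip_idx))
    dup_idx <- ok[sample.int(length(ok), min(cr$n_duplicates, length(ok)))]
    dups <- crumbs[dup_idx, ]
    dups$emit_order <- crumbs$emit_order[dup_idx] + 0.5  # right after originals
    crumbs <- bind_rows(crumbs, dups)
    log$n_duplicates <- nrow(dups)
  } else {
    log$n_duplicates <- 0L
  }

  # abandoned second trip starts: phantom ignition_on 8 s before a real start,
  # with a phantom NA-end activity row
  log$n_abandoned <- 0L
  if (cr$n_abandoned > 0 && nrow(trips) > 0) {
    ok <- trips[!trips$corrupted, ]
    ok <- ok[order(ok$start_time_utc), ]
    pickable <- which(diff(c(as.numeric(ok$start_time_utc[1]) - 1e6,
                             as.numeric(ok$start_time_utc))) > 600)
    sel <- head(pickable, cr$n_abandoned)
    for (i in sel) {
      t0 <- ok$start_time_utc[i]
      site <- sites[sites$site_id == ok$origin[i], ]
      ll <- unproject_local(site$x, site$y, cfg$center)
      crumbs <- bind_rows(crumbs, tibble(
        vehicle_id = cfg$vehicle_id, timestamp_utc = t0 - 8,
        latitude = ll$latitude, longitude = ll$longitude, speed = 0,
        odometer = NA_real_, event_type = "ignition_on",
        nearest_address = NA_character_, peak_speed = NA_real_,
        avg_event_speed = NA_real_, initial_speed = NA_real_,
        final_speed = NA_real_, trip_idx = NA_integer_,
        emit_order = next_order
      ))
      next_order <- next_order + 1
      activity <- bind_rows(activity, tibble(
        vehicle_id = cfg$vehicle_id, start_time_utc = t0 - 8,
        start_lat = ll$latitude, start_lon = ll$longitude,
        end_lat = NA_real_, end_lon = NA_real_,
        start_address = NA_character_, end_address = NA_character_,
        duration_s = 0, distance = 0, avg_speed = 0, max_speed = 0,
        n_sudden_accel = 0L, n_hard_braking = 0L, n_overspeeding = 0L,
        overspeeding_duration_s = 0
      ))
      log$n_abandoned <- log$n_abandoned + 1L
    }
  }

  # NA-end activity rows from GPS signal loss (no crumb counterpart)
  if (cr$n_na_ends > 0) {
    gaps <- trip_gaps(trips)
    times <- sample_gap_times(gaps, cr$n_na_ends)
    activity <- bind_rows(activity, tibble(
      vehicle_id = cfg$vehicle_id, start_time_utc = times,
      start_lat = cfg$center[1], start_lon = cfg$center[2],
      end_lat = NA_real_, end_lon = NA_real_,
      start_address = NA_character_, end_address = NA_character_,
      duration_s = 300, distance = 0.6, avg_speed = 15, max_speed = 25,
      n_sudden_accel = 0L, n_hard_braking = 0L, n_overspeeding = 0L,
      overspeeding_duration_s = 0
    ))
    log$n_na_ends <- length(times)
  } else {
    log$n_na_ends <- 0L
  }

  # zero start coordinates (defective-device signature in the activity feed)
  if (cr$n_zero_starts > 0) {
    gaps <- trip_gaps(trips)
    times <- sample_gap_times(gaps, cr$n_zero_starts)
    activity <- bind_rows(activity, tibble(
      vehicle_id = cfg$vehicle_id, start_time_utc = times,
      start_lat = 0, start_lon = 0,
      end_lat = cfg$center[1], end_lon = cfg$center[2],
      start_address = NA_character_, end_address = NA_character_,
      duration_s = 300, distance = 0.6, avg_speed = 15, max_speed = 25,
      n_sudden_accel = 0L, n_hard_braking = 0L, n_overspeeding = 0L,
      overspeeding_duration_s = 0
    ))
    log$n_zero_starts <- length(times)
  } else {
    log$n_zero_starts <- 0L
  }

  # an extra vehicle whose device reports only zeros for weeks
  log$defective_vehicle_id <- NA_character_
  log$defective_vehicle_crumbs <- 0L
  if (isTRUE(cr$defective_vehicle)) {
    dv <- "9999999999"
    t0 <- min(crumbs$timestamp_utc, na.rm = TRUE)
    times <- t0 + seq(0, 21 * 24 * 3600, by = cfg$idle_ping_interval_h * 3600)
    crumbs <- bind_rows(crumbs, tibble(
      vehicle_id = dv, timestamp_utc = times, latitude = 0, longitude = 0,
      speed = 0, odometer = NA_real_, event_type = "regular",
      nearest_address = NA_character_, peak_speed = NA_real_,
      avg_event_speed = NA_real_, initial_speed = NA_real_,
      final_speed = NA_real_, trip_idx = NA_integer_,
      emit_order = next_order + seq_along(times)
    ))
    log$defective_vehicle_id <- dv
    log$defective_vehicle_crumbs <- length(times)
  }

  list(crumbs = crumbs, activity = activity,
       log = log, trips = trips)
}

trip_gaps <- function(trips) {
  if (nrow(trips) < 2) {
    return(tibble(from = lubridate::as_datetime("2016-01-01"),
                  to = lubridate::as_datetime("2016-01-02")))
  }
  t <- trips[order(trips$start_time_utc), ]
  tibble(from = t$end_time_utc[-nrow(t)] + 120,
         to = t$start_time_utc[-1] - 120) %>%
    filter(.data$to > .data$from)
}

# keep injected rows from sharing a timestamp with genuine crumbs, so the
# duplicate-removal audit stays exactly attributable
avoid_timestamp_collisions <- function(times, existing) {
  ex <- as.numeric(existing)
  t <- as.numeric(times)
  for (i in seq_along(t)) {
    while (t[i] %in% ex || t[i] %in% t[-i]) t[i] <- t[i] + 1
  }
  lubridate::as_datetime(t, tz = "UTC")
}

sample_gap_times <- function(gaps, k) {
  rows <- sample.int(nrow(gaps), k, replace = TRUE)
  out <- purrr::map_vec(rows, function(r) {
    span <- as.numeric(difftime(gaps$to[r], gaps$from[r], units = "secs"))
    gaps$from[r] + round(stats::runif(1) * span)
  })
  sort(out)
}
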