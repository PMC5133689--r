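#' Assign trip ids from ignition events
#'
#' A trip is the ordered breadcrumb sequence between an `ignition_on` and the
#' next `ignition_off` of the same vehicle. Idle pings never belong to a trip.
#' A second `ignition_on` arriving within `abandoned_window_s` of an open
#' trip's start with at most one intervening crumb marks the first start as
#' "abandoned" (a known vendor data-stream quirk); any other `ignition_on`
#' while a trip is open closes the open trip at the previous crumb and flags
#' it unterminated. An `ignition_off` with no open trip quarantines that crumb.
#'
#' @param crumbs Breadcrumb tibble (any order; sorted internally by vehicle
#'   and timestamp, stable).
#' @param abandoned_window_s Seconds within which a repeated start marks the
#'   first as abandoned (default 60).
#' @return The crumbs, sorted per vehicle by time, with `trip_id` (NA outside
#'   trips) and `trip_role` (`"start"`, `"en_route"`, `"end"`, `"orphan_off"`,
#'   NA) columns.
#' @export
assign_trip_ids <- function(crumbs, abandoned_window_s = 60) {
  if (nrow(crumbs) == 0) {
    crumbs$trip_id <- character(0)
    crumbs$trip_role <- character(0)
    return(crumbs)
  }
  crumbs <- arrange(crumbs, .data$vehicle_id, .data$timestamp_utc)
  n <- nrow(crumbs)
  trip_id <- rep(NA_character_, n)
  trip_role <- rep(NA_character_, n)
  abandoned <- character(0)
  unterminated <- character(0)

  for (veh in unique(crumbs$vehicle_id)) {
    idx <- which(crumbs$vehicle_id == veh)
    open <- FALSE
    open_rows <- integer(0)
    open_start_t <- NULL
    trip_n <- 0L
    cur_id <- NULL
    close_open <- function(status) {
      if (status == "abandoned") abandoned <<- c(abandoned, cur_id)
      if (status == "unterminated") unterminated <<- c(unterminated, cur_id)
      open <<- FALSE
      open_rows <<- integer(0)
    }
    for (i in idx) {
      ev <- crumbs$event_type[i]
      t <- crumbs$timestamp_utc[i]
      if (identical(ev, "ignition_on")) {
        if (open) {
          n_between <- length(open_rows) - 1L
          dt <- as.numeric(difftime(t, open_start_t, units = "secs"))
          close_open(if (dt <= abandoned_window_s && n_between <= 1L) "abandoned" else "unterminated")
        }
        trip_n <- trip_n + 1L
        cur_id <- sprintf("%s#%04d", veh, trip_n)
        open <- TRUE
        open_start_t <- t
        open_rows <- i
        trip_id[i] <- cur_id
        trip_role[i] <- "start"
      } else if (identical(ev, "ignition_off")) {
        if (open) {
          trip_id[i] <- cur_id
          trip_role[i] <- "end"
          close_open("complete")
        } else {
          trip_role[i] <- "orphan_off"
        }
      } else if (identical(ev, "idle_ping")) {
        # parked ping: never part of a trip
      } else if (open) {
        trip_id[i] <- cur_id
        trip_role[i] <- "en_route"
        open_rows <- c(open_rows, i)
      }
    }
    if (open) close_open("unterminated")
  }
  crumbs$trip_id <- trip_id
  crumbs$trip_role <- trip_role
  structure(crumbs,
            abandoned_trips = unique(abandoned),
            unterminated_trips = unique(unterminated))
}

#' Reconstruct trips from breadcrumbs
#'
#' Groups breadcrumbs into trips via [assign_trip_ids()] and summarises one
#' row per trip, with the member crumbs as a list-column. Abandoned and
#' unterminated trips are flagged; `usable` marks complete, unflagged trips.
#'
#' @inheritParams assign_trip_ids
#' @return A tibble, one row per trip: `trip_id`, `vehicle_id`, `start_time`,
#'   `end_time`, start/end coordinates, `n_crumbs`, `abandoned`, `complete`,
#'   `usable`, and list-column `crumbs`. Quarantined `ignition_off` orphans
#'   are attached as attribute `quarantined`.
#' @export
reconstruct_trips <- function(crumbs, abandoned_window_s = 60) {
  assigned <- assign_trip_ids(crumbs, abandoned_window_s)
  abandoned <- attr(assigned, "abandoned_trips")
  unterminated <- attr(assigned, "unterminated_trips")
  in_trip <- filter(assigned, !is.na(.data$trip_id))
  if (nrow(in_trip) == 0) {
    out <- tibble(
      trip_id = character(), vehicle_id = character(),
      start_time = lubridate::as_datetime(character()),
      end_time = lubridate::as_datetime(character()),
      start_lat = double(), start_lon = double(),
      end_lat = double(), end_lon = double(),
      n_crumbs = integer(), abandoned = logical(), complete = logical(),
      usable = logical(), crumbs = list()
    )
  } else {
    out <- in_trip %>%
      tidyr::nest(crumbs = -c("trip_id", "vehicle_id")) %>%
      mutate(
        start_time = purrr::map_vec(.data$crumbs, ~ min(.x$timestamp_utc)),
        end_time = purrr::map_vec(.data$crumbs, ~ max(.x$timestamp_utc)),
        start_lat = purrr::map_dbl(.data$crumbs, ~ .x$latitude[1]),
        start_lon = purrr::map_dbl(.data$crumbs, ~ .x$longitude[1]),
        end_lat = purrr::map_dbl(.data$crumbs, ~ .x$latitude[nrow(.x)]),
        end_lon = purrr::map_dbl(.data$crumbs, ~ .x$longitude[nrow(.x)]),
        n_crumbs = purrr::map_int(.data$crumbs, nrow),
        abandoned = .data$trip_id %in% .env$abandoned,
        complete = purrr::map_lgl(.data$crumbs, ~ any(.x$trip_role == "end")),
        usable = .data$complete & !.data$abandoned
      ) %>%
      select("trip_id", "vehicle_id", "start_time", "end_time",
             "start_lat", "start_lon", "end_lat", "end_lon",
             "n_crumbs", "abandoned", "complete", "usable", "crumbs") %>%
      arrange(.data$vehicle_id, .data$start_time)
  }
  structure(out,
            quarantined = filter(assigned, .data$trip_role %in% "orphan_off"),
            unterminated_trips = unterminated)
}
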