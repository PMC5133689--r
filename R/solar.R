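#' Solar events for a date and location
#'
#' Sunrise/sunset (solar elevation -0.833 deg: refraction plus half the solar
#' disc) and civil dawn/dusk (-6 deg) from the NOAA low-accuracy solar
#' equations, iterated so the ephemeris is evaluated at the event time.
#' Documented accuracy is about +/-1 minute for |lat| < 60. Polar day/night
#' return `NA` events with the `polar` column set.
#'
#' @param lat,lon Location (decimal degrees; `lon` negative west). Scalars or
#'   vectors recycled against `date`.
#' @param date `Date` vector: the local calendar date whose solar day is
#'   wanted (events are located around that date's local noon).
#' @param tz IANA zone of `date` (used only to anchor the search near the
#'   location's noon; returned instants are UTC `POSIXct`).
#' @return Tibble: `date`, `sunrise`, `sunset`, `civil_dawn`, `civil_dusk`
#'   (UTC instants or `NA`), `daylength_h`, `polar`
#'   (`"none"`, `"polar_day"`, `"polar_night"`).
#' @export
solar_day <- function(lat, lon, date, tz = "UTC") {
  n <- max(length(lat), length(lon), length(date))
  lat <- rep_len(lat, n); lon <- rep_len(lon, n); date <- rep_len(date, n)
  res <- purrr::pmap(list(lat, lon, as.character(date)), solar_day_one)
  out <- bind_rows(res)
  out$date <- date
  select(out, "date", "sunrise", "sunset", "civil_dawn", "civil_dusk",
         "daylength_h", "polar")
}

solar_day_one <- function(lat, lon, date_chr) {
  d0 <- lubridate::ymd(date_chr, tz = "UTC")  # UTC midnight of the date
  sr <- solar_event_minutes(lat, lon, d0, zenith = 90.833, rising = TRUE)
  ss <- solar_event_minutes(lat, lon, d0, zenith = 90.833, rising = FALSE)
  cd <- solar_event_minutes(lat, lon, d0, zenith = 96, rising = TRUE)
  ck <- solar_event_minutes(lat, lon, d0, zenith = 96, rising = FALSE)
  polar <- "none"
  if (is.na(sr) || is.na(ss)) {
    # distinguish midnight sun from polar night by noon elevation
    noon_elev <- solar_declination_elevation(lat, lon, d0 + lubridate::dhours(12 - lon / 15))
    polar <- if (noon_elev > 0) "polar_day" else "polar_night"
  }
  mk <- function(m) if (is.na(m)) lubridate::as_datetime(NA) else d0 + lubridate::dminutes(m)
  tibble(
    sunrise = mk(sr), sunset = mk(ss), civil_dawn = mk(cd), civil_dusk = mk(ck),
    daylength_h = if (is.na(sr) || is.na(ss)) NA_real_ else (ss - sr) / 60,
    polar = polar
  )
}

# NOAA spreadsheet ephemeris at a Julian-century argument
noaa_sun <- function(jc) {
  rad <- pi / 180
  gmls <- (280.46646 + jc * (36000.76983 + jc * 0.0003032)) %% 360
  gmas <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  ecc <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  eqctr <- sin(rad * gmas) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(rad * 2 * gmas) * (0.019993 - 0.000101 * jc) +
    sin(rad * 3 * gmas) * 0.000289
  applong <- gmls + eqctr - 0.00569 - 0.00478 * sin(rad * (125.04 - 1934.136 * jc))
  mobl <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  obl <- mobl + 0.00256 * cos(rad * (125.04 - 1934.136 * jc))
  decl <- asin(sin(rad * obl) * sin(rad * applong)) / rad
  vary <- tan(rad * obl / 2)^2
  eqtime <- 4 / rad * (
    vary * sin(2 * rad * gmls) - 2 * ecc * sin(rad * gmas) +
      4 * ecc * vary * sin(rad * gmas) * cos(2 * rad * gmls) -
      0.5 * vary^2 * sin(4 * rad * gmls) - 1.25 * ecc^2 * sin(2 * rad * gmas)
  )
  list(decl = decl, eqtime = eqtime)
}

# minutes after the date's UTC midnight (may exceed 1440 for far-west sunsets)
solar_event_minutes <- function(lat, lon, d0_utc, zenith, rising, iters = 4) {
  rad <- pi / 180
  t <- 720
  for (k in seq_len(iters)) {
    jd <- 2440587.5 + as.numeric(d0_utc) / 86400 + t / 1440
    sun <- noaa_sun((jd - 2451545) / 36525)
    cosha <- cos(rad * zenith) / (cos(rad * lat) * cos(rad * sun$decl)) -
      tan(rad * lat) * tan(rad * sun$decl)
    if (!is.finite(cosha) || abs(cosha) > 1) return(NA_real_)
    ha <- acos(cosha) / rad
    if (rising) ha <- -ha
    t <- 720 - 4 * lon - sun$eqtime + 4 * ha
  }
  t
}

solar_declination_elevation <- function(lat, lon, instant_utc) {
  rad <- pi / 180
  jd <- 2440587.5 + as.numeric(instant_utc) / 86400
  sun <- noaa_sun((jd - 2451545) / 36525)
  mins <- (as.numeric(instant_utc) %% 86400) / 60
  tst <- (mins + sun$eqtime + 4 * lon) %% 1440
  ha <- tst / 4 - 180
  asin(sin(rad * lat) * sin(rad * sun$decl) +
         cos(rad * lat) * cos(rad * sun$decl) * cos(rad * ha)) / rad
}

#' Classify trips by light phase at departure
#'
#' Assigns each trip exactly one of `dawn`, `day`, `dusk`, `night` from the
#' trip START instant and START location: dawn = [civil dawn, sunrise),
#' day = [sunrise, sunset), dusk = [sunset, civil dusk), night otherwise.
#' Trips are classified by their start only (the profile counts trips
#' *started* in each phase); trips crossing sunset are not split.
#'
#' `not_day`, provided alongside, is the combined dawn+dusk+night tally some
#' reports prefer for a wide "night" definition.
#'
#' @param trips Trip tibble from [reconstruct_trips()] (needs `start_time`,
#'   `start_lat`, `start_lon`).
#' @param tz_polygons,fast_bbox Passed to [lookup_time_zone()].
#' @return `trips` with `tz_id`, `local_month` and `sun_phase` columns
#'   (`sun_phase` is `NA` when the zone is unresolved).
#' @export
classify_trip_light <- function(trips, tz_polygons = load_tz_polygons(),
                                fast_bbox = central_fast_bbox()) {
  trips$tz_id <- lookup_time_zone(trips$start_lat, trips$start_lon,
                                  tz_polygons, fast_bbox)
  trips$local_month <- NA_character_
  trips$sun_phase <- NA_character_
  for (zone in unique(stats::na.omit(trips$tz_id))) {
    sel <- which(trips$tz_id %in% zone)
    loc <- lubridate::with_tz(trips$start_time[sel], zone)
    ldate <- lubridate::as_date(loc)
    trips$local_month[sel] <- format(loc, "%Y-%m")
    sd <- solar_day(trips$start_lat[sel], trips$start_lon[sel], ldate, tz = zone)
    t0 <- trips$start_time[sel]
    phase <- dplyr::case_when(
      sd$polar == "polar_day" ~ "day",
      sd$polar == "polar_night" ~ "night",
      t0 >= sd$civil_dawn & t0 < sd$sunrise ~ "dawn",
      t0 >= sd$sunrise & t0 < sd$sunset ~ "day",
      t0 >= sd$sunset & t0 < sd$civil_dusk ~ "dusk",
      TRUE ~ "night"
    )
    trips$sun_phase[sel] <- phase
  }
  trips
}
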