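#' Read daily breadcrumb files
#'
#' Reads one or more delimited breadcrumb files, validates each file's header
#' against [breadcrumb_cols()], and concatenates rows in input order. Files
#' whose header set mismatches the schema are skipped (not partially read) and
#' listed in the header report; rows with event-type codes outside
#' [event_types()] are kept and flagged `event_known = FALSE`.
#'
#' @param paths Character vector of file paths.
#' @return A tibble of breadcrumbs with parsed UTC timestamps, plus columns
#'   `source_file`, `row_in_file`, `event_known`. The header report (one row
#'   per file: `path`, `ok`, `reason`) is attached as attribute
#'   `header_report` and retrievable with [header_report()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' readr::write_csv(synth_breadcrumb_rows(2), f)
#' crumbs <- read_breadcrumbs(f)
#' header_report(crumbs)
#' @export
read_breadcrumbs <- function(paths) {
  read_schema_files(paths, breadcrumb_cols(), bc_col_types(), "timestamp_utc") %>%
    finish_breadcrumbs()
}

finish_breadcrumbs <- function(res) {
  out <- res$rows
  if (nrow(out) > 0) {
    out <- out %>%
      mutate(
        timestamp_utc = parse_utc(.data$timestamp_utc),
        event_known = .data$event_type %in% event_types()
      )
    bad_speed <- !is.na(out$speed) & out$speed < 0
    if (any(bad_speed)) {
      warn(sprintf("%d breadcrumb(s) with negative speed set to NA", sum(bad_speed)))
      out$speed[bad_speed] <- NA_real_
    }
  } else {
    out <- empty_breadcrumbs()
  }
  structure(out, header_report = res$report)
}

#' Read daily trip-activity files
#'
#' Reads vendor trip summaries (one row per trip). `NA` and zero coordinates
#' pass through unmodified — cleaning is a separate, audited step
#' ([filter_trips()]).
#'
#' @inheritParams read_breadcrumbs
#' @return A tibble of trip records with attribute `header_report`.
#' @export
read_activity <- function(paths) {
  res <- read_schema_files(paths, activity_cols(), act_col_types(), "start_time_utc")
  out <- res$rows
  if (nrow(out) > 0) {
    out <- mutate(out, start_time_utc = parse_utc(.data$start_time_utc))
  } else {
    out <- empty_activity()
  }
  structure(out, header_report = res$report)
}

#' @rdname read_breadcrumbs
#' @param x A tibble returned by `read_breadcrumbs()` or `read_activity()`.
#' @export
header_report <- function(x) attr(x, "header_report")

read_schema_files <- function(paths, expected, col_types, time_col) {
  stopifnot(is.character(paths), length(paths) >= 1)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(paste0("input file not found: ", paste(missing, collapse = ", ")))
  }
  report <- tibble(path = paths, ok = NA, reason = NA_character_)
  pieces <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    hdr <- tryCatch(
      names(readr::read_csv(paths[i], n_max = 0, show_col_types = FALSE,
                            comment = "#")),
      error = function(e) abort(sprintf("cannot read '%s': %s", paths[i], conditionMessage(e)))
    )
    if (!setequal(hdr, expected)) {
      report$ok[i] <- FALSE
      report$reason[i] <- sprintf(
        "header mismatch (missing: %s; unexpected: %s)",
        paste(setdiff(expected, hdr), collapse = ",") %|empty|% "none",
        paste(setdiff(hdr, expected), collapse = ",") %|empty|% "none"
      )
      next
    }
    dat <- readr::read_csv(paths[i], col_types = col_types, na = c("", "NA"),
                           comment = "#", progress = FALSE)
    dat <- select(dat, all_of(expected))
    dat$source_file <- paths[i]
    dat$row_in_file <- seq_len(nrow(dat))
    report$ok[i] <- TRUE
    pieces[[i]] <- dat
  }
  list(rows = bind_rows(pieces), report = report)
}

`%|empty|%` <- function(x, y) if (identical(x, "")) y else x

empty_breadcrumbs <- function() {
  tibble(
    vehicle_id = character(), timestamp_utc = lubridate::as_datetime(character()),
    latitude = double(), longitude = double(), speed = double(),
    odometer = double(), event_type = character(), nearest_address = character(),
    peak_speed = double(), avg_event_speed = double(),
    initial_speed = double(), final_speed = double(),
    source_file = character(), row_in_file = integer(), event_known = logical()
  )
}

empty_activity <- function() {
  tibble(
    vehicle_id = character(), start_time_utc = lubridate::as_datetime(character()),
    start_lat = double(), start_lon = double(), end_lat = double(), end_lon = double(),
    start_address = character(), end_address = character(),
    duration_s = double(), distance = double(), avg_speed = double(),
    max_speed = double(), n_sudden_accel = integer(), n_hard_braking = integer(),
    n_overspeeding = integer(), overspeeding_duration_s = double(),
    source_file = character(), row_in_file = integer()
  )
}
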