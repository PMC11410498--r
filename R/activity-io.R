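#' Read a raw activity table
#'
#' Reads delimited text with header columns `cow_id`, `timestamp`, `steps`,
#' `motion_index`. Timestamps are ISO-8601 in the declared local timezone;
#' strings carrying an explicit UTC offset (e.g. `+02:00`, recommended
#' around daylight-saving transitions) are honored as written. Malformed
#' rows are reported with their line numbers; duplicated or non-monotone
#' timestamps within a cow are an error naming the cow and timestamp.
#'
#' @param path CSV file path.
#' @param tz Timezone of offset-less timestamps (default "Europe/Berlin",
#'   i.e. CET/CEST).
#' @return Tibble `cow_id`, `timestamp` (POSIXct in `tz`), `steps`,
#'   `motion_index`, ordered by cow and time.
#' @export
read_activity <- function(path, tz = "Europe/Berlin") {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("cow_id", "timestamp", "steps", "motion_index")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  ts <- parse_local_timestamps(raw$timestamp, tz)
  steps <- suppressWarnings(as.numeric(raw$steps))
  mi <- suppressWarnings(as.numeric(raw$motion_index))
  bad <- which(is.na(ts) | is.na(steps) | is.na(mi) | steps < 0 | mi < 0)
  if (length(bad)) {
    stop("malformed row(s) at line(s) ",
         paste(utils::head(bad + 1L, 10), collapse = ", "),
         " (1-based, counting the header as line 1)")
  }
  out <- tibble::tibble(cow_id = raw$cow_id, timestamp = ts,
                        steps = as.integer(round(steps)), motion_index = mi)
  out <- dplyr::arrange(out, .data$cow_id, .data$timestamp)
  for (cw in unique(out$cow_id)) {
    tsc <- out$timestamp[out$cow_id == cw]
    dup <- duplicated(tsc)
    if (any(dup)) {
      stop(sprintf("duplicate timestamp for cow %s at %s", cw,
                   format(tsc[dup][1], "%Y-%m-%d %H:%M")))
    }
  }
  out
}

parse_local_timestamps <- function(x, tz) {
  has_offset <- grepl("([+-][0-9]{2}:?[0-9]{2}|Z)$", x[1])
  if (has_offset) {
    lubridate::with_tz(lubridate::ymd_hms(x, quiet = TRUE), tz)
  } else {
    lubridate::ymd_hms(x, tz = tz, quiet = TRUE)
  }
}

#' Convert activity and milking schedule to the UTC (GMT) timeline
#'
#' Re-expresses every timestamp of the activity series and the milking
#' schedule on a single UTC timeline, so daylight-saving transitions leave
#' the minute axis continuous: no minute is duplicated or dropped when the
#' source device logs continuously. Schedule days whose local times cannot
#' be resolved (e.g. falling into the skipped spring-forward hour without
#' an explicit offset) raise an error naming the day.
#'
#' @param series Activity tibble from [read_activity()].
#' @param schedule Milking schedule from [read_milking_schedule()] or a raw
#'   tibble with POSIXct columns.
#' @return List with `series` and `schedule`, all POSIXct columns in UTC.
#' @export
convert_to_gmt <- function(series, schedule = NULL) {
  series$timestamp <- lubridate::with_tz(series$timestamp, "UTC")
  if (!is.null(schedule)) {
    tcols <- c("morning_start", "morning_end", "evening_start",
               "evening_end")
    for (cl in tcols) {
      if (any(is.na(schedule[[cl]]))) {
        stop("schedule day(s) with unresolvable local time: ",
             paste(schedule$date[is.na(schedule[[cl]])], collapse = ", "))
      }
      schedule[[cl]] <- lubridate::with_tz(schedule[[cl]], "UTC")
    }
  }
  list(series = series, schedule = schedule)
}

#' Read a milking/management schedule table
#'
#' Expects columns `date`, `morning_start`, `morning_end`,
#' `evening_start`, `evening_end` with local-time ISO-8601 timestamps
#' (optionally with explicit UTC offsets).
#'
#' @inheritParams read_activity
#' @return Tibble keyed by `date` with POSIXct columns in `tz`.
#' @export
read_milking_schedule <- function(path, tz = "Europe/Berlin") {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("date", "morning_start", "morning_end", "evening_start",
                "evening_end")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  out <- tibble::tibble(date = as.Date(raw$date))
  for (cl in required[-1]) out[[cl]] <- parse_local_timestamps(raw[[cl]], tz)
  ord <- with(out, morning_start < morning_end &
                morning_end < evening_start & evening_start < evening_end)
  if (any(!ord, na.rm = TRUE)) {
    stop("milking times out of order on: ",
         paste(out$date[which(!ord)], collapse = ", "))
  }
  out
}

#' Exclude unreliable and incomplete days
#'
#' Sensor-quality rule of the pipeline: a civil day (on the UTC timeline)
#' is removed when either the step count or the motion index is zero for a
#' run of strictly more than 12 h; a run spanning midnight disqualifies
#' every day it touches. Additionally the first and last calendar day of
#' each cow's raw recording and any day with fewer than a full day of
#' minutes are removed. Every exclusion is logged with cow, day, and the
#' triggering rule.
#'
#' Re-applying the function to an already-cleaned series is a no-op: the
#' boundary-day rule targets the raw recording edges (attach/detach days),
#' which a cleaned series no longer has.
#'
#' @param series Minute-level activity tibble (one or more cows),
#'   timestamps in UTC.
#' @param max_zero_hours Zero-run threshold in hours (default 12; strict
#'   inequality).
#' @return The retained series; attribute `exclusion_log` is a tibble
#'   (`cow_id`, `day`, `rule`).
#' @export
exclude_invalid_days <- function(series, max_zero_hours = 12) {
  already <- isTRUE(attr(series, "cleaned"))
  bin_min <- series_bin_minutes(series)
  per_day <- 24 * 60 / bin_min
  max_run <- max_zero_hours * 60 / bin_min

  keep_rows <- logical(nrow(series))
  logs <- list()
  for (cw in unique(series$cow_id)) {
    idx <- which(series$cow_id == cw)
    s <- series[idx, , drop = FALSE]
    day <- as.Date(s$timestamp, tz = "UTC")
    drop_days <- list()

    for (chan in c("motion_index", "steps")) {
      zr <- zero_runs(as.numeric(s[[chan]]))
      zr <- zr[zr$length > max_run, , drop = FALSE]
      if (nrow(zr)) {
        touched <- unique(unlist(lapply(seq_len(nrow(zr)), function(i) {
          unique(day[zr$start[i]:zr$end[i]])
        })))
        drop_days[[chan]] <- tibble::tibble(
          cow_id = cw, day = as.Date(touched, origin = "1970-01-01"),
          rule = sprintf("zero-run > %g h in %s", max_zero_hours, chan))
      }
    }
    if (!already) {
      drop_days$boundary <- tibble::tibble(
        cow_id = cw, day = range(day), rule = "first/last recording day")
    }
    cnt <- table(day)
    short <- as.Date(names(cnt)[cnt < per_day])
    if (length(short)) {
      drop_days$incomplete <- tibble::tibble(
        cow_id = cw, day = short, rule = "incomplete day")
    }
    dropped <- if (length(drop_days)) dplyr::bind_rows(drop_days) else
      tibble::tibble(cow_id = character(0), day = as.Date(character(0)),
                     rule = character(0))
    keep_rows[idx] <- !(day %in% dropped$day)
    logs[[cw]] <- dropped
  }
  out <- series[keep_rows, , drop = FALSE]
  if (nrow(out) == 0 && nrow(series) > 0) {
    warning("all days excluded; empty series returned")
  }
  attr(out, "cleaned") <- TRUE
  attr(out, "exclusion_log") <- dplyr::bind_rows(logs) |>
    dplyr::distinct() |> dplyr::arrange(.data$cow_id, .data$day)
  out
}

#' Resample minute-level activity to 15-min bins
#'
#' Sums motion index and steps over consecutive 15-minute bins anchored at
#' UTC midnight (:00/:15/:30/:45). Total activity per retained day is
#' conserved exactly. Bins not fully covered by minutes (which cannot occur
#' after [exclude_invalid_days()]) are dropped with a warning.
#'
#' @param series Minute-level activity tibble, UTC timestamps.
#' @param bin_minutes Target bin width (default 15).
#' @return Tibble with the same columns at `bin_minutes` resolution.
#' @export
resample_15min <- function(series, bin_minutes = 15) {
  src_bin <- series_bin_minutes(series)
  per_bin <- bin_minutes / src_bin
  out <- series |>
    dplyr::mutate(bin = lubridate::floor_date(
      .data$timestamp, paste(bin_minutes, "mins"))) |>
    dplyr::group_by(.data$cow_id, .data$bin) |>
    dplyr::summarise(steps = sum(.data$steps),
                     motion_index = sum(.data$motion_index),
                     n = dplyr::n(), .groups = "drop")
  if (any(out$n < per_bin)) {
    warning(sprintf("dropping %d partially covered bin(s)",
                    sum(out$n < per_bin)))
    out <- out[out$n >= per_bin, , drop = FALSE]
  }
  out |>
    dplyr::transmute(cow_id = .data$cow_id, timestamp = .data$bin,
                     steps = .data$steps, motion_index = .data$motion_index) |>
    dplyr::arrange(.data$cow_id, .data$timestamp)
}

#' Restrict a series to a days-in-milk window
#'
#' Keeps days whose days-in-milk (days since calving) fall inside
#' `[lo, hi]` (default 59-83, the end of early lactation, clear of calving
#' and weaning effects). Cows retaining fewer than `min_days` days are
#' flagged for exclusion from analysis.
#'
#' @param series Activity tibble (UTC), one or more cows.
#' @param meta Cow metadata with `cow_id` and `calving_date`.
#' @param lo,hi DIM bounds, inclusive (defaults 59 and 83).
#' @param min_days Minimum retained days per cow (default 15).
#' @return Filtered series; attribute `flagged_excluded` lists cow ids with
#'   fewer than `min_days` retained days (their rows are removed).
#' @export
restrict_dim_window <- function(series, meta, lo = 59, hi = 83,
                                min_days = 15) {
  stopifnot(all(c("cow_id", "calving_date") %in% names(meta)))
  calv <- meta$calving_date[match(series$cow_id, meta$cow_id)]
  if (any(is.na(calv))) {
    stop("calving date missing for cow(s): ",
         paste(unique(series$cow_id[is.na(calv)]), collapse = ", "))
  }
  dim_day <- as.integer(as.Date(series$timestamp, tz = "UTC") -
                          as.Date(calv))
  out <- series[dim_day >= lo & dim_day <= hi, , drop = FALSE]
  retained <- out |>
    dplyr::mutate(day = as.Date(.data$timestamp, tz = "UTC")) |>
    dplyr::distinct(.data$cow_id, .data$day) |>
    dplyr::count(.data$cow_id)
  flagged <- retained$cow_id[retained$n < min_days]
  out <- out[!(out$cow_id %in% flagged), , drop = FALSE]
  attr(out, "flagged_excluded") <- flagged
  out
}
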