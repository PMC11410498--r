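#' Sliding milking-anchored day/night windows
#'
#' Day is the span between morning and evening milking (about 7 h), night
#' the span between evening and next-morning milking (about 10 h); the
#' milking intervals themselves belong to neither. Because milking clock
#' times drift (notably across daylight-saving changes while the barn keeps
#' local clock time), each day's boundaries use the sliding mean of milking
#' start/end over the 7 consecutive days centered on it, computed on the
#' UTC timeline, so boundaries move smoothly rather than jumping a full
#' hour.
#'
#' @param schedule Milking schedule (UTC POSIXct columns), one row per day.
#' @param span Sliding-window length in days (default 7, centered).
#' @return Tibble per day with `day_start`, `day_end`, `night_start`,
#'   `night_end` (POSIXct UTC), `day_hours`, `night_hours`. Days lacking a
#'   full centered window of schedule (or a following day for the night
#'   end) are omitted and listed in attribute `skipped`.
#' @export
sliding_day_night <- function(schedule, span = 7) {
  stopifnot(span %% 2 == 1)
  half <- (span - 1) / 2
  sc <- dplyr::arrange(schedule, .data$date)
  tod <- function(x) as.numeric(x) %% 86400          # seconds into UTC day
  roll_mean <- function(v) {
    n <- length(v)
    vapply(seq_len(n), function(i) {
      if (i - half < 1 || i + half > n) NA_real_ else
        mean(v[(i - half):(i + half)])
    }, numeric(1))
  }
  ms <- roll_mean(tod(sc$morning_start))
  me <- roll_mean(tod(sc$morning_end))
  es <- roll_mean(tod(sc$evening_start))
  ee <- roll_mean(tod(sc$evening_end))
  day0 <- as.POSIXct(paste(sc$date, "00:00:00"), tz = "UTC")
  next_ms <- c(ms[-1], NA_real_)

  out <- tibble::tibble(
    date = sc$date,
    day_start = day0 + me,
    day_end = day0 + es,
    night_start = day0 + ee,
    night_end = day0 + 86400 + next_ms)
  ok <- stats::complete.cases(out)
  skipped <- sc$date[!ok]
  out <- out[ok, , drop = FALSE]
  out$day_hours <- as.numeric(difftime(out$day_end, out$day_start,
                                       units = "hours"))
  out$night_hours <- as.numeric(difftime(out$night_end, out$night_start,
                                         units = "hours"))
  attr(out, "skipped") <- skipped
  out
}

#' Diurnality index per cow-day
#'
#' Duration-normalized contrast of day versus night activity: with day rate
#' \eqn{R_d} = (total motion index inside the day window) / (day hours) and
#' night rate \eqn{R_n} analogous, \eqn{DI = (R_d - R_n)/(R_d + R_n)}.
#' 1 means complete diurnal activity, -1 complete nocturnal activity, 0 no
#' preference. Rates are normalized by window duration because day (~7 h)
#' and night (~10 h) are unequal. Days where both rates are zero (DI
#' undefined) or where the data do not cover both windows are skipped with
#' a warning entry in attribute `skipped`.
#'
#' @param series 15-min activity tibble for one cow (UTC).
#' @param windows Day/night windows from [sliding_day_night()].
#' @return Tibble `cow_id`, `day`, `di`, `day_rate`, `night_rate`,
#'   `day_hours`, `night_hours`.
#' @export
diurnality_index <- function(series, windows) {
  cow <- unique(series$cow_id)
  stopifnot(length(cow) == 1)
  ts <- series$timestamp
  mi <- series$motion_index
  bin_min <- series_bin_minutes(series)
  rows <- list(); skipped <- list()
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    in_day <- ts >= w$day_start & ts < w$day_end
    in_night <- ts >= w$night_start & ts < w$night_end
    # require full coverage of both windows by data bins
    need_day <- floor(w$day_hours * 60 / bin_min)
    need_night <- floor(w$night_hours * 60 / bin_min)
    if (sum(in_day) < need_day || sum(in_night) < need_night) {
      skipped[[length(skipped) + 1]] <- tibble::tibble(
        cow_id = cow, day = w$date, reason = "windows not covered by data")
      next
    }
    rd <- sum(mi[in_day]) / w$day_hours
    rn <- sum(mi[in_night]) / w$night_hours
    if (rd + rn == 0) {
      skipped[[length(skipped) + 1]] <- tibble::tibble(
        cow_id = cow, day = w$date, reason = "no activity in either window")
      next
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      cow_id = cow, day = w$date, di = (rd - rn) / (rd + rn),
      day_rate = rd, night_rate = rn,
      day_hours = w$day_hours, night_hours = w$night_hours)
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(cow_id = character(0), day = as.Date(character(0)),
                   di = numeric(0), day_rate = numeric(0),
                   night_rate = numeric(0), day_hours = numeric(0),
                   night_hours = numeric(0))
  attr(out, "skipped") <- if (length(skipped)) dplyr::bind_rows(skipped) else
    tibble::tibble(cow_id = character(0), day = as.Date(character(0)),
                   reason = character(0))
  out
}

#' Short-term deviation of milking start
#'
#' Because barn milking times follow the local clock (and so shift on the
#' UTC axis at daylight-saving changes, to which the herd adapts), the
#' model covariate is the short-term deviation, not the clock time itself:
#' the baseline for a day is the mean milking start of that day and the
#' following 6 days, and the deviation is (start of the day) minus
#' (baseline), in minutes, computed separately for morning and evening.
#' Days without a complete forward window get a missing value.
#'
#' @param schedule Milking schedule (UTC POSIXct columns).
#' @param span Forward window length in days including the day itself
#'   (default 7).
#' @return Tibble `date`, `deviation_morning`, `deviation_evening`
#'   (minutes, signed).
#' @export
milking_deviation <- function(schedule, span = 7) {
  sc <- dplyr::arrange(schedule, .data$date)
  tod_min <- function(x) (as.numeric(x) %% 86400) / 60
  fwd_dev <- function(v) {
    n <- length(v)
    vapply(seq_len(n), function(i) {
      if (i + span - 1 > n) NA_real_ else v[i] - mean(v[i:(i + span - 1)])
    }, numeric(1))
  }
  tibble::tibble(
    date = sc$date,
    deviation_morning = fwd_dev(tod_min(sc$morning_start)),
    deviation_evening = fwd_dev(tod_min(sc$evening_start)))
}
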