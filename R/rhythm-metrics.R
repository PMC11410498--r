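#' Harmonic period lengths of the 24-h day
#'
#' Harmonic periods are 24 h divided by a positive integer: 24, 12, 8, 6,
#' 4.8, 4, 3.4286... h. Rhythms at these periods are synchronized with the
#' external 24-h day. Divisors whose period falls below twice the sampling
#' interval (the Nyquist limit) are dropped with a warning.
#'
#' @param n_max Largest divisor (default 24, i.e. periods down to 1 h).
#' @param bin_minutes Sampling interval in minutes, used for the Nyquist
#'   truncation (default 15).
#' @return Numeric vector of period lengths in hours, strictly decreasing.
#' @export
harmonic_periods <- function(n_max = 24, bin_minutes = 15) {
  stopifnot(n_max >= 1)
  periods <- 24 / seq_len(n_max)
  nyq_period <- 2 * bin_minutes / 60
  keep <- periods >= nyq_period
  if (!all(keep)) {
    warning(sprintf(
      "dropping %d harmonic divisor(s) beyond the Nyquist period of %.2f h",
      sum(!keep), nyq_period))
  }
  periods[keep]
}

#' Match periodogram frequencies to harmonic periods
#'
#' A grid frequency counts as harmonic when it lies within half a grid step
#' of 1/period for some harmonic period; on the plain Fourier grid of a
#' 7-day window every harmonic is an exact grid point, so the match is
#' exact there.
#'
#' @param freqs Frequencies (cycles/hour).
#' @param harmonics Harmonic period lengths in hours, e.g.
#'   [harmonic_periods()].
#' @param grid_step Grid spacing in cycles/hour (default 1/168).
#' @return Logical vector: is each frequency harmonic? With attribute
#'   `period_h` giving the matched period (NA where non-harmonic).
#' @export
match_harmonics <- function(freqs, harmonics, grid_step = 1 / 168) {
  hf <- 1 / harmonics
  idx <- vapply(freqs, function(f) {
    d <- abs(f - hf)
    j <- which.min(d)
    if (d[j] <= grid_step / 2 + 1e-12) j else NA_integer_
  }, integer(1))
  out <- !is.na(idx)
  attr(out, "period_h") <- ifelse(out, harmonics[idx], NA_real_)
  out
}

#' Degree of functional coupling for one window
#'
#' The DFC expresses how strongly the activity in a window is coupled to
#' the external 24-h day: the ratio of significant spectral power at
#' harmonic frequencies (periods 24/n h) to the total significant spectral
#' power. 1 means all significant rhythmicity is harmonic (complete
#' adaptation to the 24-h day); if no frequency is significant the ratio is
#' undefined (division by zero) and, since no significant rhythm is
#' biologically akin to no harmonic rhythm, the record is flagged
#' degenerate and DFC is set to 0.
#'
#' @param pg Periodogram from [lomb_scargle()].
#' @param alpha Significance level on the FAP (default 0.05).
#' @param harmonics Harmonic periods in hours (default
#'   [harmonic_periods()]).
#' @param grid_step Grid spacing for harmonic matching.
#' @return One-row tibble: `dfc`, `n_sig`, `n_sig_harmonic`, `degenerate`,
#'   plus a list-column `sig_harmonics` of the significant harmonic period
#'   lengths (hours).
#' @export
dfc_window <- function(pg, alpha = 0.05, harmonics = harmonic_periods(),
                       grid_step = NULL) {
  evaluable <- isTRUE(attr(pg, "evaluable")) || nrow(pg) > 0
  sig <- if (evaluable) significant_frequencies(pg, alpha) else pg
  if (nrow(sig) == 0) {
    return(tibble::tibble(dfc = 0, n_sig = 0L, n_sig_harmonic = 0L,
                          degenerate = TRUE,
                          sig_harmonics = list(numeric(0))))
  }
  if (is.null(grid_step)) {
    grid_step <- min(diff(sort(unique(pg$freq))))
  }
  harm <- match_harmonics(sig$freq, harmonics, grid_step)
  dfc <- sum(sig$power[harm]) / sum(sig$power)
  tibble::tibble(
    dfc = dfc,
    n_sig = nrow(sig),
    n_sig_harmonic = sum(harm),
    degenerate = FALSE,
    sig_harmonics = list(attr(harm, "period_h")[harm])
  )
}

#' Sliding 7-day DFC over a cow's cleaned activity series
#'
#' One DFC record per window position, advancing one day at a time; a
#' window is labeled by its last day (the day completing 7 days of
#' history). Windows retaining fewer than `min_days` distinct days of data
#' (after cleaning removed days) are skipped and logged. The Lomb-Scargle
#' estimator tolerates the missing bins of partially retained windows.
#'
#' @param series Cleaned 15-min activity tibble for one cow (`cow_id`,
#'   `timestamp` UTC, `motion_index`, ...).
#' @param window_days Window length in days (default 7).
#' @param step_days Step between window positions (default 1).
#' @param min_days Minimum retained days per window (default 5).
#' @param alpha FAP significance level (default 0.05).
#' @param harmonics Harmonic periods (hours).
#' @return Tibble with one row per computed window: `cow_id`,
#'   `window_end_day`, `window_start_day`, `n_days`, `dfc`, `n_sig`,
#'   `n_sig_harmonic`, `degenerate`, `sig_harmonics`; attribute
#'   `skipped` logs skipped window positions.
#' @export
sliding_dfc <- function(series, window_days = 7, step_days = 1,
                        min_days = 5, alpha = 0.05,
                        harmonics = harmonic_periods()) {
  stopifnot(nrow(series) > 0)
  cow <- unique(series$cow_id)
  stopifnot(length(cow) == 1)
  day <- as.Date(series$timestamp, tz = "UTC")
  days_present <- sort(unique(day))
  span_days <- seq(min(days_present), max(days_present), by = "day")
  if (length(span_days) < window_days) {
    warning(sprintf("series for %s shorter than one %d-day window",
                    cow, window_days))
    out <- empty_dfc_records()
    attr(out, "skipped") <- tibble::tibble(cow_id = character(0),
                                           window_end_day = as.Date(character(0)),
                                           reason = character(0))
    return(out)
  }
  ends <- span_days[seq(window_days, length(span_days), by = step_days)]
  bin_min <- series_bin_minutes(series)
  n_expected <- window_days * 24 * 60 / bin_min

  rows <- list(); skipped <- list()
  for (end_day in as.list(ends)) {
    start_day <- end_day - (window_days - 1)
    in_win <- day >= start_day & day <= end_day
    n_days <- length(unique(day[in_win]))
    if (n_days < min_days) {
      skipped[[length(skipped) + 1]] <- tibble::tibble(
        cow_id = cow, window_end_day = end_day,
        reason = sprintf("only %d retained day(s) < %d", n_days, min_days))
      next
    }
    win <- series[in_win, , drop = FALSE]
    pg <- lomb_scargle(win, grid = fourier_grid(n_expected,
                                                window_days * 24))
    rec <- dfc_window(pg, alpha = alpha, harmonics = harmonics,
                      grid_step = 1 / (window_days * 24))
    rec$cow_id <- cow
    rec$window_end_day <- end_day
    rec$window_start_day <- start_day
    rec$n_days <- n_days
    rows[[length(rows) + 1]] <- rec
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else empty_dfc_records()
  out <- out[, c("cow_id", "window_end_day", "window_start_day", "n_days",
                 "dfc", "n_sig", "n_sig_harmonic", "degenerate",
                 "sig_harmonics")]
  attr(out, "skipped") <- if (length(skipped)) dplyr::bind_rows(skipped) else
    tibble::tibble(cow_id = character(0),
                   window_end_day = as.Date(character(0)),
                   reason = character(0))
  out
}

empty_dfc_records <- function() {
  tibble::tibble(cow_id = character(0),
                 window_end_day = as.Date(character(0)),
                 window_start_day = as.Date(character(0)),
                 n_days = integer(0), dfc = numeric(0), n_sig = integer(0),
                 n_sig_harmonic = integer(0), degenerate = logical(0),
                 sig_harmonics = list())
}

#' Median split of DFC records into a binary outcome
#'
#' The DFC distribution is strongly bimodal at its bounds, with median 1 in
#' the study this pipeline reproduces; the split therefore sets
#' `dfc_binary = 1` only for records attaining the maximum value 1 (within
#' 1e-9) and 0 otherwise. The empirical median is attached so the analyst
#' can verify the precondition (median equal to 1) on their own data; a
#' warning is raised when it does not hold.
#'
#' @param records DFC records with a `dfc` column.
#' @return The records with a `dfc_binary` column added; attribute
#'   `dfc_median` carries the empirical median.
#' @export
median_split <- function(records) {
  if (nrow(records) == 0) stop("no DFC records to split")
  med <- stats::median(records$dfc)
  if (abs(med - 1) > 1e-9) {
    warning(sprintf(
      "empirical DFC median is %.3f, not 1; the fixed split at 1 may not be the median split on these data", med))
  }
  records$dfc_binary <- as.integer(records$dfc > 1 - 1e-9)
  attr(records, "dfc_median") <- med
  records
}

#' Harmonic-period catalog per treatment group
#'
#' Pools the significant harmonic periods of every retained window and
#' summarizes them per group: total count, proportion per period length,
#' and average number of harmonic periods per cow (total / number of cows
#' in the group).
#'
#' @param records Output of [sliding_dfc()] (rows for all cows), with the
#'   `sig_harmonics` list-column.
#' @param meta Cow metadata with `cow_id` and `treatment`.
#' @return List with `catalog`: tibble (`treatment`, `period_h`, `n`,
#'   `proportion`) and `per_cow`: tibble (`treatment`, `n_cows`,
#'   `n_harmonic_periods`, `periods_per_cow`).
#' @export
harmonic_summary <- function(records, meta) {
  stopifnot(all(c("cow_id", "treatment") %in% names(meta)))
  unknown <- setdiff(unique(records$cow_id), meta$cow_id)
  if (length(unknown)) {
    stop("cow(s) without group label: ", paste(unknown, collapse = ", "))
  }
  long <- records |>
    dplyr::select("cow_id", "window_end_day", "sig_harmonics") |>
    tidyr::unnest_longer("sig_harmonics", values_to = "period_h") |>
    dplyr::inner_join(meta[, c("cow_id", "treatment")], by = "cow_id")

  per_cow <- meta |>
    dplyr::filter(.data$cow_id %in% unique(records$cow_id)) |>
    dplyr::count(.data$treatment, name = "n_cows") |>
    dplyr::left_join(
      dplyr::count(long, .data$treatment, name = "n_harmonic_periods"),
      by = "treatment") |>
    dplyr::mutate(
      n_harmonic_periods = dplyr::coalesce(.data$n_harmonic_periods, 0L),
      periods_per_cow = .data$n_harmonic_periods / .data$n_cows)

  if (nrow(long) == 0) {
    warning("no significant harmonic periods in any group; proportions undefined")
    catalog <- tibble::tibble(treatment = character(0),
                              period_h = numeric(0), n = integer(0),
                              proportion = numeric(0))
  } else {
    catalog <- long |>
      dplyr::count(.data$treatment, .data$period_h, name = "n") |>
      dplyr::group_by(.data$treatment) |>
      dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$treatment, dplyr::desc(.data$period_h))
  }
  list(catalog = catalog, per_cow = per_cow)
}
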