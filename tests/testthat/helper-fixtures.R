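# Shared fixtures, all built in code.

hours_15min <- function(days = 7) seq(0, by = 0.25, length.out = days * 96)

# One cow's 15-min window tibble from a function of time (hours).
make_window <- function(f, days = 7, start = "2021-09-02",
                        cow_id = "c1") {
  t <- hours_15min(days)
  tibble::tibble(
    cow_id = cow_id,
    timestamp = as.POSIXct(start, tz = "UTC") + t * 3600,
    motion_index = f(t),
    steps = 0L)
}

rectified_cosine <- function(period_h, amp = 1, phase = 0) {
  function(t) pmax(0, amp * cos(2 * pi * t / period_h + phase))
}

# Minute-level multi-day series with constant value, for cleaning tests.
make_minute_series <- function(days, value = 5, cow_id = "c1",
                               start = "2021-09-02") {
  n <- days * 1440
  tibble::tibble(
    cow_id = cow_id,
    timestamp = as.POSIXct(start, tz = "UTC") + seq_len(n) * 60 - 60,
    steps = rep(as.integer(value), n),
    motion_index = rep(as.numeric(value), n))
}

# Constant milking schedule on the UTC timeline.
make_schedule <- function(dates, morning_start = "04:00",
                          morning_end = "06:00", evening_start = "15:00",
                          evening_end = "17:00") {
  at <- function(hm) as.POSIXct(paste(dates, hm), tz = "UTC")
  tibble::tibble(
    date = dates,
    morning_start = at(morning_start), morning_end = at(morning_end),
    evening_start = at(evening_start), evening_end = at(evening_end))
}

# Constructed periodogram for direct DFC arithmetic tests.
make_periodogram <- function(freq, power, fap) {
  pg <- tibble::tibble(freq = freq, period_h = 1 / freq, power = power,
                       fap = fap)
  attr(pg, "evaluable") <- TRUE
  attr(pg, "n_samples") <- 672L
  class(pg) <- c("cow_periodogram", class(pg))
  pg
}
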