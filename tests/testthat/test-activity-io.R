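write_activity_csv <- function(df, path = tempfile(fileext = ".csv")) {
  readr::write_csv(df, path)
  path
}

minute_frame <- function(days = 3, cow_id = "c7",
                         start = "2021-01-10 00:00:00",
                         tz = "Europe/Berlin") {
  n <- days * 1440
  tibble::tibble(
    cow_id = cow_id,
    timestamp = format(as.POSIXct(start, tz = tz) + seq_len(n) * 60 - 60,
                       "%Y-%m-%dT%H:%M:%S"),
    steps = 1L, motion_index = 2.5)
}

test_that("well-formed files parse; malformed ones fail with location", {
  path <- write_activity_csv(minute_frame(3))
  s <- read_activity(path)
  expect_equal(nrow(s), 3 * 1440)
  expect_s3_class(s$timestamp, "POSIXct")

  dup <- minute_frame(1)
  dup <- rbind(dup, dup[100, ])
  expect_error(read_activity(write_activity_csv(dup)),
               "duplicate timestamp for cow c7")

  nocol <- minute_frame(1)[, c("cow_id", "timestamp", "motion_index")]
  expect_error(read_activity(write_activity_csv(nocol)), "steps")

  bad <- minute_frame(1)
  bad$motion_index[5] <- -1
  expect_error(read_activity(write_activity_csv(bad)), "line")
})

test_that("local-to-GMT conversion is exact, invertible, and DST-safe", {
  # CET (UTC+1): 05:00 local -> 04:00 UTC
  s <- tibble::tibble(
    cow_id = "c1",
    timestamp = as.POSIXct("2021-01-10 05:00:00", tz = "Europe/Berlin"),
    steps = 0L, motion_index = 0)
  utc <- convert_to_gmt(s)$series$timestamp
  expect_equal(format(utc, "%H:%M", tz = "UTC"), "04:00")

  # winter day round-trip local -> UTC -> local is the identity
  w <- minute_frame(1, start = "2021-01-10 00:00:00")
  parsed <- read_activity(write_activity_csv(w))
  back <- lubridate::with_tz(convert_to_gmt(parsed)$series$timestamp,
                             "Europe/Berlin")
  expect_equal(as.numeric(back), as.numeric(parsed$timestamp))

  # spring-forward: device logs continuously; the local day has 23 h but
  # all 1440 UTC-anchored minutes survive conversion
  utc_start <- as.POSIXct("2021-03-28 00:00:00", tz = "UTC")
  dev_log <- tibble::tibble(
    cow_id = "c1",
    timestamp = format(lubridate::with_tz(utc_start + seq_len(1440) * 60 - 60,
                                          "Europe/Berlin"),
                       "%Y-%m-%dT%H:%M:%S%z"),
    steps = 1L, motion_index = 1)
  parsed <- read_activity(write_activity_csv(dev_log))
  conv <- convert_to_gmt(parsed)$series
  expect_equal(nrow(conv), 1440)
  expect_equal(sum(duplicated(conv$timestamp)), 0)
  expect_equal(as.numeric(diff(range(conv$timestamp)), units = "mins"),
               1439)
})

test_that("zero-run exclusion is strict at 12 h and spans midnight", {
  s <- make_minute_series(5)
  day <- as.Date(s$timestamp, tz = "UTC")
  days <- sort(unique(day))

  # 13-h zero-run inside day 3 in motion index only
  s13 <- s
  i <- which(day == days[3])[1:(13 * 60)]
  s13$motion_index[i] <- 0
  out <- exclude_invalid_days(s13)
  expect_false(days[3] %in% as.Date(out$timestamp, tz = "UTC"))
  log <- attr(out, "exclusion_log")
  expect_true(any(grepl("zero-run", log$rule) & log$day == days[3]))

  # exactly 12 h: kept (strict inequality)
  s12 <- s
  s12$motion_index[which(day == days[3])[1:(12 * 60)]] <- 0
  out12 <- exclude_invalid_days(s12)
  expect_true(days[3] %in% as.Date(out12$timestamp, tz = "UTC"))

  # run spanning midnight removes both touched days
  sm <- s
  j <- which(day %in% days[3:4])
  mid <- which(day == days[4])[1]
  sm$steps[(mid - 7 * 60):(mid + 7 * 60)] <- 0L
  outm <- exclude_invalid_days(sm)
  kept <- as.Date(outm$timestamp, tz = "UTC")
  expect_false(any(days[3:4] %in% kept))
})

test_that("boundary days are dropped once and cleaning is idempotent", {
  s <- make_minute_series(5)
  out1 <- exclude_invalid_days(s)
  expect_equal(length(unique(as.Date(out1$timestamp, tz = "UTC"))), 3)
  out2 <- exclude_invalid_days(out1)
  expect_equal(nrow(out2), nrow(out1))
  expect_equal(out2$timestamp, out1$timestamp)
})

test_that("15-min resampling sums, aligns, and conserves totals", {
  s <- make_minute_series(3, value = 2)
  s <- exclude_invalid_days(s)
  r <- resample_15min(s)
  expect_equal(unique(r$motion_index), 30)  # 15 x 2
  expect_true(all(as.numeric(r$timestamp) %% (15 * 60) == 0))
  expect_equal(nrow(r), 96)  # one retained day

  # random series: totals preserved exactly per day
  set.seed(8)
  s2 <- make_minute_series(4)
  s2$motion_index <- runif(nrow(s2), 0, 10)
  r2 <- resample_15min(s2)
  expect_equal(sum(r2$motion_index), sum(s2$motion_index))
  by_day <- function(x) tapply(x$motion_index,
                               as.Date(x$timestamp, tz = "UTC"), sum)
  expect_equal(unname(by_day(r2)), unname(by_day(s2)))

  # all-zero day resamples to 96 zero bins
  s3 <- make_minute_series(1, value = 0)
  r3 <- resample_15min(s3)
  expect_equal(nrow(r3), 96)
  expect_true(all(r3$motion_index == 0))
})

test_that("DIM restriction keeps 59-83 and flags cows with < 15 days", {
  meta <- tibble::tibble(cow_id = "c1",
                         calving_date = as.Date("2021-09-02") - 59)
  s <- make_minute_series(25)   # DIM 59..83
  out <- restrict_dim_window(s, meta)
  expect_equal(length(unique(as.Date(out$timestamp, tz = "UTC"))), 25)
  expect_length(attr(out, "flagged_excluded"), 0)

  s14 <- make_minute_series(14) # only 14 retained days
  out14 <- restrict_dim_window(s14, meta)
  expect_equal(attr(out14, "flagged_excluded"), "c1")
  expect_equal(nrow(out14), 0)

  out1 <- restrict_dim_window(make_minute_series(25), meta, lo = 60,
                              hi = 60, min_days = 1)
  expect_equal(length(unique(as.Date(out1$timestamp, tz = "UTC"))), 1)

  expect_error(restrict_dim_window(s, tibble::tibble(
    cow_id = "c1", calving_date = as.Date(NA))), "calving date")
})
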