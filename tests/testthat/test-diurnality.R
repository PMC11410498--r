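test_that("constant schedules give constant day/night boundaries", {
  dates <- as.Date("2021-09-01") + 0:13
  sched <- make_schedule(dates)
  w <- sliding_day_night(sched)
  # centered 7-day window: first/last 3 days (and the last day, which has
  # no following morning) are skipped
  expect_equal(nrow(w), 14 - 6 - 1)
  expect_true(all(format(w$day_start, "%H:%M") == "06:00"))
  expect_true(all(format(w$day_end, "%H:%M") == "15:00"))
  expect_true(all(format(w$night_start, "%H:%M") == "17:00"))
  expect_true(all(format(w$night_end, "%H:%M") == "04:00"))
  expect_equal(unique(w$day_hours), 9)
  expect_equal(unique(w$night_hours), 11)
})

test_that("one +70-min evening outlier shifts the sliding boundary by 10 min", {
  dates <- as.Date("2021-09-01") + 0:14
  sched <- make_schedule(dates)
  k <- 8
  sched$evening_start[k] <- sched$evening_start[k] + 70 * 60
  sched$evening_end[k] <- sched$evening_end[k] + 70 * 60
  w <- sliding_day_night(sched)
  base <- as.POSIXct(paste(w$date, "15:00:00"), tz = "UTC")
  shift_min <- as.numeric(w$day_end - base, units = "mins")
  affected <- abs(as.numeric(w$date - dates[k])) <= 3
  expect_equal(shift_min[affected], rep(10, sum(affected)))
  expect_equal(shift_min[!affected], rep(0, sum(!affected)))
})

test_that("boundaries move smoothly across a DST transition week", {
  # milking follows the local clock: 05:00 local is 04:00 UTC before the
  # spring-forward on 2021-03-28 and 03:00 UTC after it
  dates <- as.Date("2021-03-21") + 0:13
  loc <- function(d, hm) as.POSIXct(paste(d, hm), tz = "Europe/Berlin")
  sched <- tibble::tibble(
    date = dates,
    morning_start = loc(dates, "05:00:00"),
    morning_end = loc(dates, "07:00:00"),
    evening_start = loc(dates, "16:00:00"),
    evening_end = loc(dates, "18:00:00"))
  sched <- convert_to_gmt(make_minute_series(1), sched)$schedule
  w <- sliding_day_night(sched)
  tod_min <- (as.numeric(w$day_start) %% 86400) / 60
  jumps <- abs(diff(tod_min))
  expect_true(all(jumps <= 60 / 7 + 1e-6))  # never the raw 60-min jump
  expect_gt(sum(jumps), 0)                  # but the boundary does move
})

test_that("DI hits its boundary values and symmetry point", {
  dates <- as.Date("2021-09-01") + 0:8
  sched <- make_schedule(dates)
  w <- sliding_day_night(sched)
  base <- make_window(function(t) rep(0, length(t)), days = 9,
                      start = "2021-09-01")
  in_win <- function(ts, lo, hi) ts >= lo & ts < hi
  day_of <- function(ts) as.Date(ts, tz = "UTC")

  mk <- function(day_val, night_val) {
    s <- base
    for (i in seq_len(nrow(w))) {
      s$motion_index[in_win(s$timestamp, w$day_start[i], w$day_end[i])] <-
        day_val
      s$motion_index[in_win(s$timestamp, w$night_start[i],
                            w$night_end[i])] <- night_val
    }
    s
  }
  di_day <- diurnality_index(mk(4, 0), w)
  expect_true(nrow(di_day) >= 1)
  expect_true(all(di_day$di == 1))
  di_night <- diurnality_index(mk(0, 4), w)
  expect_true(all(di_night$di == -1))
  di_eq <- diurnality_index(mk(3, 3), w)
  expect_true(all(abs(di_eq$di) < 1e-12))
})

test_that("DI is antisymmetric under day/night swap and scale-invariant", {
  dates <- as.Date("2021-09-01") + 0:8
  sched <- make_schedule(dates)
  w <- sliding_day_night(sched)
  set.seed(12)
  s <- make_window(function(t) runif(length(t), 0, 10), days = 9,
                   start = "2021-09-01")
  di1 <- diurnality_index(s, w)
  # swap: move each day-window activity into the night window and back
  s2 <- s
  for (i in seq_len(nrow(w))) {
    in_day <- s$timestamp >= w$day_start[i] & s$timestamp < w$day_end[i]
    in_night <- s$timestamp >= w$night_start[i] & s$timestamp < w$night_end[i]
    dr <- sum(s$motion_index[in_day]) / w$day_hours[i]
    nr <- sum(s$motion_index[in_night]) / w$night_hours[i]
    # rescale contents so the day rate becomes the night rate and back
    s2$motion_index[in_day] <- s$motion_index[in_day] * nr / dr
    s2$motion_index[in_night] <- s$motion_index[in_night] * dr / nr
  }
  di2 <- diurnality_index(s2, w)
  expect_equal(di2$di, -di1$di, tolerance = 1e-9)
  s3 <- s
  s3$motion_index <- s3$motion_index * 11.7
  expect_equal(diurnality_index(s3, w)$di, di1$di, tolerance = 1e-12)
})

test_that("milking deviation uses the forward 7-day baseline", {
  dates <- as.Date("2021-09-01") + 0:13
  sched <- make_schedule(dates)
  dev0 <- milking_deviation(sched)
  expect_equal(dev0$deviation_morning[1:7], rep(0, 7))
  expect_true(all(is.na(dev0$deviation_morning[9:14])))

  # considered day 14 min late, following 6 on time: 14 - mean(14,0,...,0)
  late <- sched
  late$morning_start[1] <- late$morning_start[1] + 14 * 60
  d <- milking_deviation(late)
  expect_equal(d$deviation_morning[1], 12)

  # considered day on time, a later day 14 min late: 0 - 2
  late2 <- sched
  late2$morning_start[4] <- late2$morning_start[4] + 14 * 60
  d2 <- milking_deviation(late2)
  expect_equal(d2$deviation_morning[1], -2)

  # adding a constant to every start leaves deviations unchanged
  shifted <- sched
  shifted$morning_start <- shifted$morning_start + 23 * 60
  expect_equal(milking_deviation(shifted)$deviation_morning,
               dev0$deviation_morning)
})
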