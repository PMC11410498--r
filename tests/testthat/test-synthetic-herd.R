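small_scenario <- function(...) {
  herd_scenario(n_cows_per_group = c(NOC = 1, DTC = 1, WDC = 1),
                days = 10, seed = 321, ...)
}

test_that("the generator is deterministic and per-cow streams are stable", {
  s1 <- simulate_herd(small_scenario())
  s2 <- simulate_herd(small_scenario())
  expect_identical(s1$activity, s2$activity)
  expect_identical(s1$schedule, s2$schedule)
  expect_identical(s1$ground_truth, s2$ground_truth)

  # adding a cow to a group must not change the existing cows' draws
  bigger <- herd_scenario(n_cows_per_group = c(NOC = 1, DTC = 1, WDC = 2),
                          days = 10, seed = 321)
  s3 <- simulate_herd(bigger)
  for (cw in unique(s1$activity$cow_id)) {
    expect_identical(s1$activity[s1$activity$cow_id == cw, ],
                     s3$activity[s3$activity$cow_id == cw, ],
                     label = paste("activity of", cw))
  }
})

test_that("scenario validation rejects impossible settings", {
  expect_error(herd_scenario(days = 0), "nonpositive")
  expect_error(herd_scenario(n_cows_per_group = c(NOC = 0, DTC = 1,
                                                  WDC = 1)), "empty")
  expect_error(herd_scenario(diurnal_fraction = 1.2), "diurnal_fraction")
  expect_error(herd_scenario(harmonic_amplitudes = c("24" = -1)),
               "amplitudes")
  sim <- simulate_herd(small_scenario())
  expect_true(all(sim$activity$motion_index >= 0))
  expect_true(all(sim$activity$steps >= 0))
})

test_that("a pure 24-h scenario peaks at 24 h in every 7-day window", {
  sc <- herd_scenario(n_cows_per_group = c(NOC = 1, DTC = 1, WDC = 1),
                      days = 12, seed = 5,
                      harmonic_amplitudes = c("24" = 10),
                      noise_sd = 0, diurnal_fraction = 0.5,
                      milking = list(morning_start = "05:00",
                                     morning_end = "07:00",
                                     evening_start = "16:00",
                                     evening_end = "18:00",
                                     jitter_sd = 0, bump_height = 0,
                                     bump_width = 30),
                      dropout = list(prob = 0, min_hours = 1,
                                     max_hours = 1),
                      estrus = list(prob = 0, multiplier = 1,
                                    noise_inflation = 1))
  sim <- simulate_herd(sc)
  gmt <- convert_to_gmt(sim$activity, sim$schedule)
  a15 <- resample_15min(exclude_invalid_days(gmt$series))
  cw <- a15[a15$cow_id == "cow001", ]
  day <- as.Date(cw$timestamp, tz = "UTC")
  days <- sort(unique(day))
  for (end in seq(7, length(days))) {
    win <- cw[day >= days[end - 6] & day <= days[end], ]
    pg <- lomb_scargle(win)
    expect_equal(pg$period_h[which.max(pg$power)], 24, tolerance = 1e-9)
  }
})

test_that("dominant-period recovery holds for every harmonic at high SNR", {
  for (p in c(24, 12, 8, 4.8, 24 / 7)) {
    amps <- stats::setNames(10, as.character(p))
    sc <- herd_scenario(n_cows_per_group = c(NOC = 1, DTC = 1, WDC = 1),
                        days = 9, seed = 99,
                        harmonic_amplitudes = amps, noise_sd = 1,
                        diurnal_fraction = 0.5,
                        dropout = list(prob = 0, min_hours = 1,
                                       max_hours = 1),
                        estrus = list(prob = 0, multiplier = 1,
                                      noise_inflation = 1))
    sim <- simulate_herd(sc)
    gmt <- convert_to_gmt(sim$activity, sim$schedule)
    a15 <- resample_15min(exclude_invalid_days(gmt$series))
    cw <- a15[a15$cow_id == "cow001", ]
    day <- as.Date(cw$timestamp, tz = "UTC")
    days <- sort(unique(day))
    win <- cw[day >= days[1] & day <= days[7], ]
    pg <- lomb_scargle(win)
    grid_step <- 1 / 168
    expect_lt(abs(pg$freq[which.max(pg$power)] - 1 / p), grid_step + 1e-12,
              label = sprintf("peak frequency for period %.3f h", p))
  }
})

test_that("diurnal fraction maps monotonically onto the computed DI", {
  mean_di <- vapply(c(0.2, 0.5, 0.8), function(f) {
    sc <- herd_scenario(n_cows_per_group = c(NOC = 1, DTC = 1, WDC = 1),
                        days = 10, seed = 11, diurnal_fraction = f,
                        dropout = list(prob = 0, min_hours = 1,
                                       max_hours = 1))
    sim <- simulate_herd(sc)
    gmt <- convert_to_gmt(sim$activity, sim$schedule)
    a15 <- resample_15min(exclude_invalid_days(gmt$series))
    wins <- sliding_day_night(gmt$schedule)
    di <- dplyr::bind_rows(lapply(split(a15, a15$cow_id),
                                  diurnality_index, windows = wins))
    mean(di$di)
  }, numeric(1))
  expect_true(all(diff(mean_di) > 0))
})

test_that("full diurnal fraction yields DI = 1 on every complete day", {
  sc <- herd_scenario(n_cows_per_group = c(NOC = 1, DTC = 1, WDC = 1),
                      days = 10, seed = 77, diurnal_fraction = 1,
                      dropout = list(prob = 0, min_hours = 1,
                                     max_hours = 1))
  sim <- simulate_herd(sc)
  gmt <- convert_to_gmt(sim$activity, sim$schedule)
  # note: no zero-run cleaning here — a fully diurnal cow has silent
  # nights longer than the 12-h sensor-failure rule by construction
  a15 <- resample_15min(gmt$series)
  wins <- sliding_day_night(gmt$schedule)
  di <- dplyr::bind_rows(lapply(split(a15, a15$cow_id), diurnality_index,
                                windows = wins))
  expect_true(nrow(di) > 0)
  expect_true(all(di$di == 1))
})

test_that("a forced 13-h dropout removes that cow-day in cleaning", {
  sc <- small_scenario()
  sim <- simulate_herd(sc)
  gmt <- convert_to_gmt(sim$activity, sim$schedule)
  s <- gmt$series[gmt$series$cow_id == "cow001", ]
  day <- as.Date(s$timestamp, tz = "UTC")
  target <- sort(unique(day))[4]
  i <- which(day == target)[1:(13 * 60)]
  s$motion_index[i] <- 0
  s$steps[i] <- 0L
  out <- exclude_invalid_days(s)
  expect_false(target %in% as.Date(out$timestamp, tz = "UTC"))
})

test_that("estrus injection is the identity at multiplier 1 and attenuates DFC", {
  sc <- herd_scenario(n_cows_per_group = c(NOC = 1, DTC = 1, WDC = 1),
                      days = 11, seed = 13, diurnal_fraction = 0.5,
                      red_noise = list(sd = 0, tau_hours = 1),
                      milking = list(morning_start = "05:00",
                                     morning_end = "07:00",
                                     evening_start = "16:00",
                                     evening_end = "18:00",
                                     jitter_sd = 0, bump_height = 0,
                                     bump_width = 30),
                      dropout = list(prob = 0, min_hours = 1,
                                     max_hours = 1),
                      estrus = list(prob = 0, multiplier = 1,
                                    noise_inflation = 1))
  sim <- simulate_herd(sc)
  s <- sim$activity[sim$activity$cow_id == "cow001", ]
  days <- sort(unique(as.Date(s$timestamp, tz = "UTC")))

  expect_identical(inject_estrus(s, days[3], multiplier = 1,
                                 noise_inflation = 1), s)
  expect_error(inject_estrus(s, as.Date("1999-01-01"), 0.5),
               "outside the series span")

  pipeline_dfc <- function(series) {
    gmt <- convert_to_gmt(series, sim$schedule)
    a15 <- resample_15min(exclude_invalid_days(gmt$series))
    day <- as.Date(a15$timestamp, tz = "UTC")
    win <- a15[day >= days[2] & day <= days[8], ]
    dfc_window(lomb_scargle(win))
  }
  base <- pipeline_dfc(s)

  # multiplier 0 on all 7 window days: no harmonic structure left
  set.seed(1)
  flat <- inject_estrus(s, days[2:8], multiplier = 0, noise_inflation = 2)
  rec_flat <- pipeline_dfc(flat)
  expect_equal(rec_flat$dfc, 0)
  expect_true(rec_flat$degenerate)

  # multiplier 0.2 on one day cannot increase the window DFC
  set.seed(2)
  one <- inject_estrus(s, days[5], multiplier = 0.2, noise_inflation = 2)
  rec_one <- pipeline_dfc(one)
  expect_lte(rec_one$dfc, base$dfc)
})

test_that("scenario tables round-trip through CSV in local time", {
  sim <- simulate_herd(small_scenario())
  dir <- tempfile("scen")
  paths <- write_scenario_tables(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- read_activity(file.path(dir, "activity.csv"))
  expect_equal(nrow(back), nrow(sim$activity))
  expect_equal(as.numeric(back$timestamp),
               as.numeric(sim$activity$timestamp))
  expect_equal(back$motion_index, sim$activity$motion_index,
               tolerance = 1e-12)
  sched <- read_milking_schedule(file.path(dir, "milking_schedule.csv"))
  expect_equal(as.numeric(sched$morning_start),
               as.numeric(sim$schedule$morning_start))
})
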