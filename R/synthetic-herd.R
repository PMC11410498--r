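#' Define a synthetic herd scenario
#'
#' Bundles and validates all knobs of the synthetic herd generator. The
#' defaults emulate the cow-calf-contact study layout: three treatment
#' groups (no contact NOC, daytime contact DTC, whole-day contact WDC) in
#' two herds, minute-resolution motion index with circadian (24 h) plus
#' ultradian (12, 8, 4.8, 24/7 h) harmonic components, milking at about
#' 05:00 and 16:00 local time (CET/CEST), milking-anchored activity bumps,
#' a mildly diurnal activity distribution, occasional estrus days on which
#' rhythm amplitude collapses and noise inflates, and sporadic sensor
#' dropout producing long zero-runs.
#'
#' @param n_cows_per_group Named counts for NOC, DTC, WDC (defaults
#'   36/25/18, the study's group sizes).
#' @param days Simulated calendar span in days (default 29: days-in-milk
#'   57-85, so the 59-83 analysis window survives boundary-day exclusion).
#' @param sampling Bin width of the raw data in minutes (default 1).
#' @param harmonic_amplitudes Named vector period(h) -> amplitude
#'   (motion-index units per minute).
#' @param baseline Mean motion index per minute (default 20).
#' @param diurnal_fraction Target share of activity inside the day window
#'   (default 0.55, a mild diurnal preference; 1 = fully diurnal,
#'   0 = fully nocturnal).
#' @param milking Nominal local milking times and per-day jitter SD in
#'   minutes.
#' @param estrus Probability that a cow has an estrus day in the span,
#'   amplitude multiplier and noise inflation applied on that day, and
#'   `di_shift`: the increase of the day-window activity share on estrus
#'   days (estrus restlessness is expressed mainly in daytime, raising the
#'   diurnality index while the harmonic structure collapses).
#' @param dropout Per cow-day probability of a zero-run and its duration
#'   range in hours.
#' @param noise_sd Additive white Gaussian noise SD (motion-index units).
#' @param red_noise Autocorrelated (AR(1)) noise component: `sd` in
#'   motion-index units and correlation time `tau_hours`. Bout-like
#'   activity fluctuations are strongly autocorrelated, and this is what
#'   puts spectral power at non-harmonic frequencies, so that some windows
#'   have DFC strictly between 0 and 1.
#' @param cow_amplitude_log_sd SD of the per-cow lognormal multiplier on
#'   all harmonic amplitudes (default 0.6): some cows are strongly
#'   rhythmic, others sit near the detection threshold, which is what
#'   makes the window-level DFC bimodal rather than uniformly 1.
#' @param cow_diurnal_sd SD of the per-cow jitter on `diurnal_fraction`
#'   (default 0.03); ignored at the exact extremes 0 and 1. This is the
#'   source of between-cow variance in the diurnality index.
#' @param day_amplitude_log_sd SD of the per-day lognormal multiplier on
#'   the rhythm amplitude (default 0.4): a cow's rhythmicity waxes and
#'   wanes from day to day, so cows near the detection threshold produce
#'   both significant and rhythm-free weeks.
#' @param dim_at_start Days in milk on the first simulated day (default 57).
#' @param start_date First simulated calendar date.
#' @param tz Local timezone of the farm clock.
#' @param seed Root RNG seed; per-cow streams are derived by stable hashing
#'   of the cow id, so adding a cow leaves the others unchanged.
#' @return Validated scenario object (class `herd_scenario`).
#' @export
herd_scenario <- function(n_cows_per_group = c(NOC = 36, DTC = 25, WDC = 18),
                          days = 29,
                          sampling = 1,
                          harmonic_amplitudes = c("24" = 1.2, "12" = 1.1,
                                                  "8" = 0.7, "4.8" = 2.6,
                                                  "3.42857142857143" = 3),
                          baseline = 20,
                          diurnal_fraction = 0.46,
                          milking = list(morning_start = "05:00",
                                         morning_end = "07:00",
                                         evening_start = "16:00",
                                         evening_end = "18:00",
                                         jitter_sd = 5,
                                         bump_height = 10,
                                         bump_width = 30),
                          estrus = list(prob = 0.3, multiplier = 0.1,
                                        noise_inflation = 2,
                                        di_shift = 0.09),
                          dropout = list(prob = 0.02, min_hours = 2,
                                         max_hours = 16),
                          noise_sd = 8,
                          red_noise = list(sd = 2, tau_hours = 1.5),
                          cow_amplitude_log_sd = 1,
                          cow_diurnal_sd = 0.02,
                          day_amplitude_log_sd = 0.4,
                          dim_at_start = 57,
                          start_date = as.Date("2021-09-01"),
                          tz = "Europe/Berlin",
                          seed = 20210901) {
  n_cows_per_group <- unlist(n_cows_per_group)
  harmonic_amplitudes <- unlist(harmonic_amplitudes)
  start_date <- as.Date(start_date)
  stopifnot(all(c("NOC", "DTC", "WDC") %in% names(n_cows_per_group)))
  if (any(n_cows_per_group <= 0)) stop("empty treatment group")
  if (days <= 0) stop("nonpositive number of days")
  if (any(harmonic_amplitudes < 0)) stop("harmonic amplitudes must be >= 0")
  if (diurnal_fraction < 0 || diurnal_fraction > 1) {
    stop("diurnal_fraction must lie in [0, 1]")
  }
  structure(list(
    n_cows_per_group = n_cows_per_group, days = days, sampling = sampling,
    harmonic_amplitudes = harmonic_amplitudes, baseline = baseline,
    diurnal_fraction = diurnal_fraction, milking = milking, estrus = estrus,
    dropout = dropout, noise_sd = noise_sd, red_noise = red_noise,
    cow_amplitude_log_sd = cow_amplitude_log_sd,
    cow_diurnal_sd = cow_diurnal_sd,
    day_amplitude_log_sd = day_amplitude_log_sd,
    dim_at_start = dim_at_start,
    start_date = start_date, tz = tz, seed = seed),
    class = "herd_scenario")
}

#' Simulate a herd of activity series with known ground truth
#'
#' Generates per-cow minute-level activity, the herd milking schedule, cow
#' metadata, and a ground-truth table. Activity per minute is a rectified
#' (clipped at zero) sum of cosine components at the configured harmonic
#' periods with per-cow random phases, modulated by a day/night envelope
#' that hits the target diurnal fraction, plus symmetric triangular bumps
#' at each milking start, plus Gaussian noise. On estrus days the harmonic
#' amplitudes are multiplied by the estrus multiplier and noise is inflated.
#' Dropout sets both channels to zero over a contiguous run.
#'
#' @param scenario A [herd_scenario()].
#' @return List with `activity` (tibble: cow_id, timestamp local tz, steps,
#'   motion_index), `schedule` (milking schedule, local tz), `meta` (cow
#'   metadata), `ground_truth` (per cow-day truths).
#' @export
simulate_herd <- function(scenario) {
  stopifnot(inherits(scenario, "herd_scenario"))
  sc <- scenario
  dates <- seq(sc$start_date, by = "day", length.out = sc$days)

  schedule <- simulate_schedule(dates, sc)
  sched_utc <- convert_to_gmt_schedule(schedule)

  meta <- make_meta(sc, dates)
  acts <- vector("list", nrow(meta))
  gts <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    sim <- simulate_cow(meta$cow_id[i], meta$estrus_dates[[i]], sched_utc, sc)
    acts[[i]] <- sim$activity
    gts[[i]] <- sim$ground_truth
  }
  list(activity = dplyr::bind_rows(acts),
       schedule = schedule,
       meta = meta,
       ground_truth = dplyr::bind_rows(gts))
}

simulate_schedule <- function(dates, sc) {
  set.seed(as.integer((sc$seed + 1) %% 2147483647))
  mk <- sc$milking
  jit <- function(n) round(stats::rnorm(n, 0, mk$jitter_sd))
  loc <- function(date, hm, j) {
    as.POSIXct(paste(date, paste0(hm, ":00")), tz = sc$tz) + 60 * j
  }
  n <- length(dates)
  tibble::tibble(
    date = dates,
    morning_start = loc(dates, mk$morning_start, jit(n)),
    morning_end = loc(dates, mk$morning_end, jit(n)),
    evening_start = loc(dates, mk$evening_start, jit(n)),
    evening_end = loc(dates, mk$evening_end, jit(n)))
}

convert_to_gmt_schedule <- function(schedule) {
  for (cl in c("morning_start", "morning_end", "evening_start",
               "evening_end")) {
    schedule[[cl]] <- lubridate::with_tz(schedule[[cl]], "UTC")
  }
  schedule
}

make_meta <- function(sc, dates) {
  set.seed(as.integer((sc$seed + 2) %% 2147483647))
  groups <- rep(names(sc$n_cows_per_group), sc$n_cows_per_group)
  n <- length(groups)
  cow_id <- sprintf("cow%03d", seq_len(n))
  herd <- rep(c("polled", "horned"), length.out = n)
  parity <- sample(c("primiparous", "multiparous"), n, replace = TRUE,
                   prob = c(0.35, 0.65))
  lact <- ifelse(parity == "primiparous", 1L, sample(2:5, n, replace = TRUE))
  calving <- sc$start_date - sc$dim_at_start
  meta <- tibble::tibble(
    cow_id = cow_id, herd = herd, treatment = groups, parity = parity,
    lactation_number = lact, calving_date = calving,
    health_exclusion = FALSE)
  # estrus days drawn per cow from its own stream so they are stable
  meta$estrus_dates <- lapply(meta$cow_id, function(cw) {
    set.seed(cow_seed(sc$seed + 3, cw))
    if (stats::runif(1) < sc$estrus$prob) {
      sample(dates[-c(1, length(dates))], 1)
    } else as.Date(character(0))
  })
  meta
}

simulate_cow <- function(cow_id, estrus_dates, sched_utc, sc) {
  set.seed(cow_seed(sc$seed, cow_id))
  amp_factor <- stats::rlnorm(1, 0, sc$cow_amplitude_log_sd)
  f_cow <- if (sc$diurnal_fraction %in% c(0, 1)) sc$diurnal_fraction else
    min(0.95, max(0.05, sc$diurnal_fraction +
                    stats::rnorm(1, 0, sc$cow_diurnal_sd)))
  bin_min <- sc$sampling
  n_per_day <- 24 * 60 / bin_min
  t0 <- lubridate::with_tz(
    as.POSIXct(paste(sc$start_date, "00:00:00"), tz = sc$tz), "UTC")
  # simulate on the UTC minute grid covering the local-time span
  n_min <- sc$days * n_per_day
  ts <- t0 + seq(0, by = 60 * bin_min, length.out = n_min)
  th <- as.numeric(ts - ts[1]) / 3600

  periods <- as.numeric(names(sc$harmonic_amplitudes))
  # ultradian phases are free per cow; the circadian (24-h) phase is
  # entrained by the shared light/milking cycle: peak near 11:00 UTC
  # (mid-day window), with small per-cow jitter
  phases <- stats::runif(length(periods), 0, 2 * pi)
  is24 <- periods == 24
  phases[is24] <- -2 * pi * 11 / 24 + stats::rnorm(sum(is24), 0, 0.3)
  day_utc <- as.Date(ts, tz = "UTC")
  estrus_min <- day_utc %in% estrus_dates

  day_idx <- as.integer(day_utc - min(day_utc)) + 1L
  day_factor <- stats::rlnorm(max(day_idx), 0, sc$day_amplitude_log_sd)
  amps <- matrix(sc$harmonic_amplitudes * amp_factor, nrow = n_min,
                 ncol = length(periods), byrow = TRUE)
  amps <- amps * day_factor[day_idx]
  amps[estrus_min, ] <- amps[estrus_min, ] * sc$estrus$multiplier
  harm <- rowSums(amps * cos(outer(2 * pi * th, 1 / periods) +
                               matrix(phases, n_min, length(periods),
                                      byrow = TRUE)))

  env <- day_night_envelope(ts, sched_utc, f_cow)
  if (any(estrus_min) && !is.null(sc$estrus$di_shift) &&
      sc$estrus$di_shift != 0 && !(f_cow %in% c(0, 1))) {
    f_est <- min(0.95, f_cow + sc$estrus$di_shift)
    env_est <- day_night_envelope(ts, sched_utc, f_est)
    env[estrus_min] <- env_est[estrus_min]
  }
  bumps <- milking_bumps(ts, sched_utc,
                         sc$milking$bump_height * amp_factor *
                           day_factor[day_idx],
                         sc$milking$bump_width)
  noise_sd <- ifelse(estrus_min, sc$noise_sd * sc$estrus$noise_inflation,
                     sc$noise_sd)
  noise <- stats::rnorm(n_min, 0, noise_sd)
  if (sc$red_noise$sd > 0) {
    phi <- exp(-bin_min / (60 * sc$red_noise$tau_hours))
    red <- stats::filter(stats::rnorm(n_min, 0,
                                      sc$red_noise$sd * sqrt(1 - phi^2)),
                         phi, method = "recursive")
    noise <- noise + as.numeric(red)
  }
  # envelope multiplies the whole signal so extreme diurnal fractions
  # (0 or 1) silence the opposite window entirely
  mi <- pmax(0, env * (sc$baseline + harm + bumps + noise))
  steps <- stats::rpois(n_min, lambda = 0.25 * mi)

  # sensor dropout: contiguous zero-runs starting on randomly hit days
  dropped <- rep(FALSE, n_min)
  for (d in seq_len(sc$days)) {
    if (stats::runif(1) < sc$dropout$prob) {
      dur_min <- round(60 * stats::runif(1, sc$dropout$min_hours,
                                         sc$dropout$max_hours))
      start <- (d - 1) * n_per_day + sample.int(n_per_day, 1)
      idx <- start:min(start + dur_min - 1, n_min)
      dropped[idx] <- TRUE
    }
  }
  mi[dropped] <- 0
  steps[dropped] <- 0

  activity <- tibble::tibble(
    cow_id = cow_id,
    timestamp = lubridate::with_tz(ts, sc$tz),
    steps = as.integer(steps), motion_index = mi)

  dominant <- periods[which.max(sc$harmonic_amplitudes)]
  gt <- tibble::tibble(cow_id = cow_id, day = unique(day_utc)) |>
    dplyr::mutate(
      true_dominant_period = dominant,
      true_diurnal_fraction = f_cow,
      estrus = .data$day %in% estrus_dates,
      dropout_minutes = vapply(.data$day, function(dd) {
        sum(dropped[day_utc == dd])
      }, numeric(1)))
  list(activity = activity, ground_truth = gt)
}

# Piecewise day/night multiplier normalized to mean 1 over day+night time.
# f is the target share of activity falling inside the day window; milking
# intervals (in neither window) get the average of the two levels. Uses the
# schedule's actual per-day windows: day = [morning end, evening start),
# night = [evening end, next morning start).
day_night_envelope <- function(ts, sched_utc, f) {
  n <- length(ts)
  sc <- dplyr::arrange(sched_utc, .data$date)
  next_ms <- c(sc$morning_start[-1],
               sc$morning_start[nrow(sc)] + 86400)
  t_day <- mean(as.numeric(sc$evening_start - sc$morning_end,
                           units = "hours"))
  t_night <- mean(as.numeric(difftime(next_ms, sc$evening_end,
                                      units = "hours")))
  lev_day <- (f / t_day) * (t_day + t_night)
  lev_night <- ((1 - f) / t_night) * (t_day + t_night)
  in_day <- rep(FALSE, n); in_night <- rep(FALSE, n)
  for (i in seq_len(nrow(sc))) {
    in_day <- in_day | (ts >= sc$morning_end[i] & ts < sc$evening_start[i])
    in_night <- in_night | (ts >= sc$evening_end[i] & ts < next_ms[i])
  }
  # milking intervals belong to neither window; at the extremes (f = 0 or
  # 1) they are silenced too so that *all* activity falls inside the one
  # target window
  lev_milk <- if (f == 0 || f == 1) 0 else (lev_day + lev_night) / 2
  env <- rep(lev_milk, n)
  env[in_day] <- lev_day
  env[in_night] <- lev_night
  env
}

milking_bumps <- function(ts, sched_utc, height, width_min) {
  bump <- rep(0, length(ts))
  height <- rep_len(height, length(ts))
  starts <- c(sched_utc$morning_start, sched_utc$evening_start)
  half <- width_min * 60 / 2
  tnum <- as.numeric(ts)
  for (s in as.numeric(starts)) {
    d <- abs(tnum - s)
    sel <- d < half
    bump[sel] <- bump[sel] + height[sel] * (1 - d[sel] / half)
  }
  bump
}

#' Inject an estrus-like perturbation into an activity series
#'
#' On the listed days the rhythmic structure is attenuated by shrinking
#' each value toward the series mean by `multiplier`, and noise is inflated
#' by adding zero-mean Gaussian noise of SD `noise_sd * (noise_inflation -
#' 1)`; the result is rectified at zero. Other days are bit-identical to
#' the input. With `multiplier = 1` and `noise_inflation = 1` the output is
#' identical to the input (no RNG draw is made). This mimics the observed
#' estrus signature — loss of harmonic rhythmicity with erratic extra
#' activity — without claiming behavioral realism.
#'
#' @param series Activity tibble for one cow (any timezone).
#' @param days Date vector (UTC days) to perturb; must lie in the series
#'   span.
#' @param multiplier Amplitude multiplier in [0, inf); 0 erases rhythm.
#' @param noise_inflation Noise inflation factor (>= 1).
#' @param noise_sd Base noise SD used for the inflation term (default 6).
#' @return The perturbed series.
#' @export
inject_estrus <- function(series, days, multiplier,
                          noise_inflation = 1, noise_sd = 6) {
  stopifnot(multiplier >= 0, noise_inflation >= 1)
  day_utc <- as.Date(series$timestamp, tz = "UTC")
  unknown <- setdiff(as.character(days), as.character(unique(day_utc)))
  if (length(unknown)) {
    stop("days outside the series span: ", paste(unknown, collapse = ", "))
  }
  if (multiplier == 1 && noise_inflation == 1) return(series)
  sel <- day_utc %in% as.Date(days)
  mi <- series$motion_index
  m <- mean(mi)
  mi[sel] <- m + multiplier * (mi[sel] - m)
  if (noise_inflation > 1) {
    mi[sel] <- mi[sel] + stats::rnorm(sum(sel), 0,
                                      noise_sd * (noise_inflation - 1))
  }
  series$motion_index <- pmax(0, mi)
  series
}

#' Write scenario tables as CSV
#'
#' Serializes the three input tables (activity, milking schedule, cow
#' metadata) plus the ground truth in the pipeline's CSV dialect:
#' comma-separated, header row, ISO-8601 local timestamps with explicit
#' UTC offset (unambiguous across daylight-saving transitions).
#'
#' @param sim Output of [simulate_herd()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_scenario_tables <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  iso <- function(x) format(x, "%Y-%m-%dT%H:%M:%S%z")
  act <- dplyr::mutate(sim$activity, timestamp = iso(.data$timestamp))
  sch <- dplyr::mutate(sim$schedule,
                       dplyr::across(dplyr::where(lubridate::is.POSIXct), iso))
  meta <- dplyr::mutate(sim$meta, estrus_dates = vapply(
    .data$estrus_dates, function(d) paste(d, collapse = ";"), character(1)))
  paths <- file.path(dir, c("activity.csv", "milking_schedule.csv",
                            "cow_meta.csv", "ground_truth.csv"))
  readr::write_csv(act, paths[1])
  readr::write_csv(sch, paths[2])
  readr::write_csv(meta, paths[3])
  readr::write_csv(sim$ground_truth, paths[4])
  invisible(paths)
}
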