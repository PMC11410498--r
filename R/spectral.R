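#' Fourier-style frequency grid for a sliding activity window
#'
#' The grid is \eqn{f_k = k / (L \cdot o)} cycles/hour for
#' \eqn{k = 1, \ldots, \lfloor n/2 \rfloor \cdot o}, where \eqn{L} is the
#' nominal window length in hours and \eqn{o} the oversampling factor. For a
#' complete 7-day window at 15-min sampling (n = 672, L = 168) this yields
#' 336 frequencies, and every harmonic of the 24-h day (period 24/n h) falls
#' on an exact grid point. Grid covers 1/L up to the Nyquist frequency of
#' the sampling.
#'
#' @param n_samples Number of samples in a complete window.
#' @param window_hours Nominal window length in hours (default 168 = 7 d).
#' @param oversample Integer oversampling factor (default 1, the plain
#'   Fourier grid).
#' @return Numeric vector of frequencies in cycles/hour, strictly
#'   increasing.
#' @export
fourier_grid <- function(n_samples, window_hours = 168, oversample = 1) {
  stopifnot(n_samples >= 2, window_hours > 0, oversample >= 1)
  k_max <- floor(n_samples / 2) * oversample
  seq_len(k_max) / (window_hours * oversample)
}

#' Lomb-Scargle periodogram of an activity window
#'
#' Least-squares spectral power of an (possibly gapped) activity series on
#' an explicit frequency grid. The input is mean-subtracted; at each
#' frequency the classical Scargle phase offset \eqn{\tau} orthogonalizes
#' the sine and cosine regressors and the power is the fraction of total
#' variance removed by the sinusoid fit ("standard" normalization, in
#' [0, 1]). Per-frequency false-alarm probabilities are attached via
#' [baluev_fap()].
#'
#' Windows with fewer than 8 samples or zero variance carry no evaluable
#' rhythm: an empty periodogram with attribute `evaluable = FALSE` is
#' returned, which downstream feeds the DFC = 0 degenerate rule.
#'
#' @param window Either a data frame with columns `timestamp` (POSIXct) and
#'   `motion_index`, or a numeric vector of activity values (then `times_h`
#'   must be given).
#' @param grid Frequency grid in cycles/hour; defaults to [fourier_grid()]
#'   on the nominal window length.
#' @param times_h Sample times in hours (only when `window` is a bare
#'   numeric vector).
#' @param window_hours Nominal window length used for the default grid.
#' @return A tibble of class `cow_periodogram` with columns `freq`
#'   (cycles/h), `period_h`, `power`, `fap`; attributes `n_samples`,
#'   `times_h`, `evaluable`, `window_span`.
#' @export
lomb_scargle <- function(window, grid = NULL, times_h = NULL,
                         window_hours = 168) {
  if (is.data.frame(window)) {
    stopifnot(all(c("timestamp", "motion_index") %in% names(window)))
    t0 <- min(window$timestamp)
    times_h <- as.numeric(difftime(window$timestamp, t0, units = "hours"))
    y <- as.numeric(window$motion_index)
    span <- range(window$timestamp)
  } else {
    y <- as.numeric(window)
    stopifnot(!is.null(times_h), length(times_h) == length(y))
    span <- range(times_h)
  }
  ok <- stats::complete.cases(times_h, y)
  times_h <- times_h[ok]; y <- y[ok]
  n <- length(y)
  if (is.null(grid)) grid <- fourier_grid(n, window_hours)

  if (n < 8 || stats::var(y) == 0) {
    pg <- tibble::tibble(freq = numeric(0), period_h = numeric(0),
                         power = numeric(0), fap = numeric(0))
    return(new_periodogram(pg, n, times_h, span, evaluable = FALSE))
  }

  y <- y - mean(y)
  sst <- sum(y^2)
  w <- 2 * pi * grid
  wt <- outer(times_h, w)                       # n x m phase matrix
  tau_w <- atan2(colSums(sin(2 * wt)), colSums(cos(2 * wt))) / 2
  ph <- sweep(wt, 2, tau_w)
  ct <- cos(ph); st <- sin(ph)
  yc <- colSums(y * ct); ys <- colSums(y * st)
  cc <- colSums(ct * ct); ss <- colSums(st * st)
  eps <- 1e-12 * n
  delta <- ifelse(cc > eps, yc^2 / cc, 0) + ifelse(ss > eps, ys^2 / ss, 0)
  power <- pmin(pmax(delta / sst, 0), 1)

  fap <- baluev_fap(power, n, fmax = max(grid), times_h = times_h)
  pg <- tibble::tibble(freq = grid, period_h = 1 / grid,
                       power = power, fap = fap)
  new_periodogram(pg, n, times_h, span, evaluable = TRUE)
}

new_periodogram <- function(pg, n, times_h, span, evaluable) {
  attr(pg, "n_samples") <- n
  attr(pg, "times_h") <- times_h
  attr(pg, "window_span") <- span
  attr(pg, "evaluable") <- evaluable
  class(pg) <- c("cow_periodogram", class(pg))
  pg
}

#' Baluev false-alarm probability for Lomb-Scargle power
#'
#' Aliasing-free upper bound on the probability that pure noise produces a
#' periodogram peak at least as high as `power` anywhere over the searched
#' frequency range \eqn{[0, f_{max}]} (extreme-value bound on the
#' continuous-frequency scan). Formulated for the standard normalization
#' (power = fraction of variance explained, in [0, 1]):
#' \deqn{\mathrm{FAP}(Z) = 1 - (1 - (1-Z)^{N_K/2})\, e^{-\tau(Z)},}
#' \deqn{\tau(Z) = f_{max}\sqrt{4\pi\,\mathrm{var}(t)}\;
#'       (1-Z)^{(N_K-1)/2} \sqrt{N_H Z / 2},}
#' with \eqn{N_H = n - 1}, \eqn{N_K = n - 3}. The bound is sharp for low
#' FAP and conservative otherwise, so thresholding at a level alpha is a
#' valid (slightly conservative) test.
#'
#' @param power Normalized power value(s) in [0, 1]; power exactly 1 (a
#'   noiseless tone absorbing all variance) is accepted and maps to FAP 0.
#' @param n_samples Number of samples in the window.
#' @param fmax Maximum searched frequency (cycles/hour); alternatively pass
#'   `grid` and its maximum is used.
#' @param times_h Sample times in hours; their variance sets the effective
#'   bandwidth. If omitted, a uniform window of `n_samples` spanning
#'   `window_hours` is assumed.
#' @param grid Optional frequency grid, used only for `fmax`.
#' @param window_hours Fallback window span when `times_h` is missing.
#' @return FAP value(s) in [0, 1].
#' @export
baluev_fap <- function(power, n_samples, fmax = NULL, times_h = NULL,
                       grid = NULL, window_hours = 168) {
  if (is.null(fmax)) {
    stopifnot(!is.null(grid))
    fmax <- max(grid)
  }
  if (any(power < 0 | power > 1, na.rm = TRUE)) {
    stop("normalized power must lie in [0, 1]")
  }
  if (is.null(times_h)) {
    times_h <- seq(0, window_hours, length.out = n_samples)
  }
  n <- n_samples
  nh <- n - 1
  nk <- n - 3
  var_t <- mean((times_h - mean(times_h))^2)
  teff <- sqrt(4 * pi * var_t)
  z <- pmin(pmax(power, 0), 1)
  fap_single <- (1 - z)^(nk / 2)
  tau <- fmax * teff * (1 - z)^((nk - 1) / 2) * sqrt(nh * z / 2)
  pmin(pmax(1 - (1 - fap_single) * exp(-tau), 0), 1)
}

#' Significant frequencies of a periodogram
#'
#' Frequencies whose Baluev false-alarm probability is at or below `alpha`
#' (default 0.05), with their powers. An empty result is allowed and means
#' no significant rhythm in the window.
#'
#' @param pg A periodogram from [lomb_scargle()].
#' @param alpha Significance level on the FAP (default 0.05).
#' @return Tibble with columns `freq`, `period_h`, `power`, `fap`.
#' @export
significant_frequencies <- function(pg, alpha = 0.05) {
  stopifnot(is.data.frame(pg), alpha >= 0, alpha <= 1)
  pg[pg$fap <= alpha, c("freq", "period_h", "power", "fap"), drop = FALSE]
}
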