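#' Remove outliers by the 1.5-IQR rule
#'
#' Drops values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`. Quartiles use the
#' linear-interpolation convention (`stats::quantile` type 7). With fewer
#' than 4 observations the rule is ill-defined and the input is returned
#' unchanged with a warning.
#'
#' @param values Numeric vector (e.g. diurnality-index observations).
#' @param k Fence multiplier (default 1.5).
#' @return The retained values; attribute `removed` holds the indices of
#'   dropped observations (into the input vector).
#' @export
remove_outliers_iqr <- function(values, k = 1.5) {
  if (length(values) < 4) {
    warning("fewer than 4 observations; IQR filter not applied")
    attr(values, "removed") <- integer(0)
    return(values)
  }
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  lo <- q[1] - k * iqr
  hi <- q[2] + k * iqr
  removed <- which(values < lo | values > hi)
  out <- if (length(removed)) values[-removed] else values
  attr(out, "removed") <- removed
  out
}

#' Assemble the cow-day model frame
#'
#' Joins the per-window DFC records (keyed by their window-end day), the
#' per-day DI records, the evening milking-start deviation, and the cow
#' metadata into one observation table for the mixed models. The estrus
#' flag marks days listed in the metadata's `estrus_dates`. Factor
#' reference levels are NOC (treatment), diestrus (estrus = no), and
#' primiparous (parity).
#'
#' @param dfc_records Output of [sliding_dfc()] bound over cows, after
#'   [median_split()].
#' @param di_records Output of [diurnality_index()] bound over cows.
#' @param deviations Output of [milking_deviation()].
#' @param meta Cow metadata (cow_id, herd, treatment, parity,
#'   lactation_number, estrus_dates).
#' @return Tibble with one row per cow-day: outcomes `dfc_binary` and
#'   `di`, covariates `treatment`, `estrus`, `parity`, `dev_evening`,
#'   grouping columns `herd`, `cow_id`, `lactation_number`, `dataset_id`,
#'   `day`, `day_index`.
#' @export
assemble_model_frame <- function(dfc_records, di_records, deviations,
                                 meta) {
  dfc <- dfc_records |>
    dplyr::transmute(cow_id = .data$cow_id, day = .data$window_end_day,
                     dfc = .data$dfc, dfc_binary = .data$dfc_binary)
  di <- di_records[, c("cow_id", "day", "di")]
  frame <- dplyr::full_join(dfc, di, by = c("cow_id", "day")) |>
    dplyr::left_join(deviations[, c("date", "deviation_evening")],
                     by = c(day = "date")) |>
    dplyr::rename(dev_evening = "deviation_evening") |>
    dplyr::inner_join(
      meta[, c("cow_id", "herd", "treatment", "parity",
               "lactation_number", "estrus_dates")],
      by = "cow_id")
  frame$estrus <- mapply(function(d, ed) d %in% as.Date(ed),
                         frame$day, frame$estrus_dates)
  frame$estrus_dates <- NULL
  frame$treatment <- factor(frame$treatment,
                            levels = c("NOC", "DTC", "WDC"))
  frame$estrus <- factor(ifelse(frame$estrus, "estrus", "diestrus"),
                         levels = c("diestrus", "estrus"))
  frame$parity <- factor(frame$parity,
                         levels = c("primiparous", "multiparous"))
  frame$dataset_id <- interaction(frame$cow_id, frame$lactation_number,
                                  drop = TRUE)
  frame <- dplyr::arrange(frame, .data$cow_id, .data$day)
  frame <- frame |>
    dplyr::group_by(.data$dataset_id) |>
    dplyr::mutate(day_index = as.integer(.data$day - min(.data$day))) |>
    dplyr::ungroup()
  frame
}

#' Fit the binomial DFC model
#'
#' Generalized linear mixed model (logit link) for the median-split DFC:
#' fixed effects contact-time treatment (reference NOC), estrus (reference
#' diestrus), and the evening milking-start deviation in minutes; random
#' intercepts for lactation nested in cow nested in herd; and an AR(1)
#' serially correlated latent process over consecutive days within each
#' cow dataset (the binomial analogue of AR(1) residual covariance).
#' Datasets with no outcome variation (all 0 or all 1) cannot inform a
#' binomial fit and are excluded with a log entry. Estimates are reported
#' as odds ratios with Wald 95% CIs versus the reference levels.
#'
#' @param frame Model frame from [assemble_model_frame()] (rows with
#'   missing modeled columns are dropped).
#' @param ar1 Include the AR(1) latent process (default TRUE).
#' @return A `cow_model_result` list: `tidy` (term, estimate, se, ci_lo,
#'   ci_hi, odds_ratio, or_lo, or_hi, p_value), `varcorr`, `n_obs`,
#'   `n_clusters`, `excluded_clusters`, `fit` (the glmmTMB object).
#' @export
fit_dfc_model <- function(frame, ar1 = TRUE) {
  cols <- c("dfc_binary", "treatment", "estrus", "dev_evening",
            "herd", "cow_id", "lactation_number", "dataset_id",
            "day_index")
  d <- frame[stats::complete.cases(frame[, cols]), cols]
  if (length(unique(d$dfc_binary)) < 2) {
    stop("no variation in the binary DFC outcome; model not fit")
  }
  var_by_cluster <- tapply(d$dfc_binary, d$dataset_id,
                           function(x) length(unique(x)) > 1)
  excluded <- names(var_by_cluster)[!var_by_cluster]
  d <- d[!(d$dataset_id %in% excluded), , drop = FALSE]
  d$dataset_id <- droplevels(d$dataset_id)
  if (length(unique(d$dataset_id)) < 2) {
    stop("fewer than 2 clusters with outcome variation")
  }
  d$day_f <- factor(d$day_index,
                    levels = seq(0, max(d$day_index)))
  form <- build_formula("dfc_binary",
                        c("treatment", "estrus", "dev_evening"), d, ar1)
  fit <- glmmTMB::glmmTMB(form, data = d, family = stats::binomial())
  res <- summarize_fit(fit, d, exponentiate = TRUE)
  res$excluded_clusters <- excluded
  res
}

#' Fit the Gaussian DI model
#'
#' Linear mixed model for the (outlier-filtered) diurnality index: fixed
#' effects treatment, estrus, and parity; random intercepts for lactation
#' nested in cow nested in herd; AR(1) serial correlation over days within
#' each cow dataset. Estimates are on the identity scale with Wald 95%
#' CIs. Marginal (population-level) treatment means are attached.
#'
#' @inheritParams fit_dfc_model
#' @param iqr_filter Apply [remove_outliers_iqr()] to `di` first
#'   (default TRUE).
#' @return A `cow_model_result` list as in [fit_dfc_model()], plus
#'   `emmeans`: per-treatment estimated means.
#' @export
fit_di_model <- function(frame, ar1 = TRUE, iqr_filter = TRUE) {
  cols <- c("di", "treatment", "estrus", "parity", "herd", "cow_id",
            "lactation_number", "dataset_id", "day_index")
  d <- frame[stats::complete.cases(frame[, cols]), cols]
  if (nrow(d) == 0) stop("no complete DI observations")
  if (stats::var(d$di) == 0) {
    stop("no variation in the DI outcome; model not fit")
  }
  if (iqr_filter) {
    filt <- remove_outliers_iqr(d$di)
    removed <- attr(filt, "removed")
    if (length(removed)) d <- d[-removed, , drop = FALSE]
  }
  d$dataset_id <- droplevels(d$dataset_id)
  d$day_f <- factor(d$day_index, levels = seq(0, max(d$day_index)))
  form <- build_formula("di", c("treatment", "estrus", "parity"), d, ar1)
  fit <- glmmTMB::glmmTMB(form, data = d, family = stats::gaussian())
  res <- summarize_fit(fit, d, exponentiate = FALSE)
  res$emmeans <- marginal_treatment_means(fit, d)
  res
}

# Fixed-effect terms that are constant in the data (single observed factor
# level, zero-variance covariate) are dropped so the design matrix stays
# full rank on degenerate inputs.
build_formula <- function(response, fixed, d, ar1) {
  keep <- vapply(fixed, function(v) {
    x <- d[[v]]
    if (is.factor(x)) length(unique(as.character(x))) > 1 else
      stats::var(x) > 0
  }, logical(1))
  fixed <- fixed[keep]
  if (!length(fixed)) fixed <- "1"
  rhs <- paste(c(fixed, "(1 | herd / cow_id / lactation_number)",
                 if (ar1) "ar1(day_f + 0 | dataset_id)"),
               collapse = " + ")
  stats::as.formula(paste(response, "~", rhs))
}

summarize_fit <- function(fit, d, exponentiate) {
  co <- summary(fit)$coefficients$cond
  tidy <- tibble::tibble(
    term = rownames(co),
    estimate = co[, "Estimate"],
    se = co[, "Std. Error"],
    ci_lo = co[, "Estimate"] - 1.96 * co[, "Std. Error"],
    ci_hi = co[, "Estimate"] + 1.96 * co[, "Std. Error"],
    p_value = co[, ncol(co)])
  if (exponentiate) {
    tidy$odds_ratio <- exp(tidy$estimate)
    tidy$or_lo <- exp(tidy$ci_lo)
    tidy$or_hi <- exp(tidy$ci_hi)
  }
  structure(list(
    tidy = tidy,
    varcorr = glmmTMB::VarCorr(fit),
    n_obs = nrow(d),
    n_clusters = length(unique(d$dataset_id)),
    converged = isTRUE(fit$sdr$pdHess),
    fit = fit), class = "cow_model_result")
}

# Population-level predicted mean per treatment, averaging over the other
# fixed-effect levels present in the data (balanced grid, random effects
# at zero).
marginal_treatment_means <- function(fit, d) {
  grid <- expand.grid(treatment = levels(d$treatment),
                      estrus = levels(droplevels(d$estrus)),
                      parity = levels(droplevels(d$parity)))
  grid$herd <- NA; grid$cow_id <- NA; grid$lactation_number <- NA
  grid$dataset_id <- NA; grid$day_f <- NA
  pr <- stats::predict(fit, newdata = grid, re.form = NA,
                       allow.new.levels = TRUE)
  tibble::tibble(treatment = grid$treatment, pred = pr) |>
    dplyr::group_by(.data$treatment) |>
    dplyr::summarise(emmean = mean(.data$pred), .groups = "drop")
}

#' @export
print.cow_model_result <- function(x, ...) {
  cat(sprintf("Mixed model on %d observations, %d clusters%s\n",
              x$n_obs, x$n_clusters,
              if (x$converged) "" else " (no convergence)"))
  print(x$tidy, n = Inf)
  invisible(x)
}

#' Simulate a cow-day model frame from known coefficients
#'
#' Recovery harness for the two inferential models: draws nested random
#' intercepts (herd, cow, lactation-in-cow), an AR(1) latent day process
#' per cow dataset, and then binary (logit) and Gaussian outcomes from the
#' given fixed-effect coefficients. The default design matches the study
#' scale: 36/25/18 cows over 23 days (about 1,800 cow-day rows).
#'
#' @param n_cows_per_group Named NOC/DTC/WDC counts.
#' @param n_days Days per cow dataset.
#' @param coefs_binary Named fixed effects on the log-odds scale
#'   (intercept, treatmentDTC, treatmentWDC, estrus, dev_evening per min).
#' @param coefs_gauss Named fixed effects on the identity scale
#'   (intercept, treatmentDTC, treatmentWDC, estrus, parity_multi).
#' @param sd_cow,sd_lact,sd_herd Random-intercept SDs (shared latent scale).
#' @param ar1_phi,ar1_sd AR(1) correlation and marginal SD of the latent
#'   day process.
#' @param sigma Gaussian residual SD.
#' @param estrus_prob Probability a cow has one estrus day in the span.
#' @param dev_sd SD of the evening milking-deviation covariate (minutes).
#' @param seed RNG seed.
#' @return Model frame as from [assemble_model_frame()] (with true linear
#'   predictors attached as attributes `eta_binary`, `eta_gauss`).
#' @export
simulate_model_frame <- function(n_cows_per_group = c(NOC = 36, DTC = 25,
                                                      WDC = 18),
                                 n_days = 23,
                                 coefs_binary = c(intercept = 1.19,
                                                  treatmentDTC = 0,
                                                  treatmentWDC = 0,
                                                  estrus = -2.303,
                                                  dev_evening = -0.02),
                                 coefs_gauss = c(intercept = 0.10,
                                                 treatmentDTC = 0,
                                                 treatmentWDC = 0,
                                                 estrus = 0.12,
                                                 parity_multi = 0),
                                 sd_cow = 1.5, sd_lact = 0.5,
                                 sd_herd = 0.2,
                                 ar1_phi = 0.5, ar1_sd = 1,
                                 sigma = 0.15,
                                 estrus_prob = 0.5,
                                 dev_sd = 5,
                                 seed = 1) {
  set.seed(seed)
  groups <- rep(names(n_cows_per_group), n_cows_per_group)
  n_cows <- length(groups)
  cow_id <- sprintf("cow%03d", seq_len(n_cows))
  herd <- rep(c("polled", "horned"), length.out = n_cows)
  parity <- sample(c("primiparous", "multiparous"), n_cows, replace = TRUE)
  lact <- ifelse(parity == "primiparous", 1L,
                 sample(2:5, n_cows, replace = TRUE))
  u_herd <- stats::rnorm(2, 0, sd_herd)
  names(u_herd) <- c("polled", "horned")
  u_cow <- stats::rnorm(n_cows, 0, sd_cow)
  u_lact <- stats::rnorm(n_cows, 0, sd_lact)

  # shared day-level covariate: evening milking deviation
  dev_evening <- stats::rnorm(n_days, 0, dev_sd)

  rows <- vector("list", n_cows)
  for (i in seq_len(n_cows)) {
    e <- stats::rnorm(n_days)
    lat <- numeric(n_days)
    lat[1] <- e[1]
    for (t in 2:n_days) {
      lat[t] <- ar1_phi * lat[t - 1] + sqrt(1 - ar1_phi^2) * e[t]
    }
    lat <- ar1_sd * lat
    estrus <- rep(FALSE, n_days)
    if (stats::runif(1) < estrus_prob) {
      estrus[sample.int(n_days, 1)] <- TRUE
    }
    tr <- groups[i]
    xb_b <- coefs_binary["intercept"] +
      (tr == "DTC") * coefs_binary["treatmentDTC"] +
      (tr == "WDC") * coefs_binary["treatmentWDC"] +
      estrus * coefs_binary["estrus"] +
      dev_evening * coefs_binary["dev_evening"]
    xb_g <- coefs_gauss["intercept"] +
      (tr == "DTC") * coefs_gauss["treatmentDTC"] +
      (tr == "WDC") * coefs_gauss["treatmentWDC"] +
      estrus * coefs_gauss["estrus"] +
      (parity[i] == "multiparous") * coefs_gauss["parity_multi"]
    re <- u_herd[herd[i]] + u_cow[i] + u_lact[i]
    eta_b <- xb_b + re + lat
    eta_g <- xb_g + (re + lat) * (sigma / 4)   # scaled to DI units
    rows[[i]] <- tibble::tibble(
      cow_id = cow_id[i], herd = herd[i], treatment = tr,
      parity = parity[i], lactation_number = lact[i],
      day = as.Date("2021-01-01") + seq_len(n_days) - 1,
      day_index = seq_len(n_days) - 1L,
      dev_evening = dev_evening,
      estrus = estrus,
      dfc_binary = stats::rbinom(n_days, 1, stats::plogis(eta_b)),
      di = stats::rnorm(n_days, eta_g, sigma))
  }
  frame <- dplyr::bind_rows(rows)
  frame$treatment <- factor(frame$treatment, levels = c("NOC", "DTC", "WDC"))
  frame$estrus <- factor(ifelse(frame$estrus, "estrus", "diestrus"),
                         levels = c("diestrus", "estrus"))
  frame$parity <- factor(frame$parity,
                         levels = c("primiparous", "multiparous"))
  frame$dataset_id <- interaction(frame$cow_id, frame$lactation_number,
                                  drop = TRUE)
  frame
}
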