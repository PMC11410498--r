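# cowrhythms

Circadian and ultradian activity-rhythm analysis for dairy herds, built
around minute-resolution leg-accelerometer data (step counts and motion
index, MI) from cows kept with or without contact to their calves.

Prolonged cow-calf contact (CCC) is increasingly adopted on dairy farms,
and a natural question is whether calves that freely visit their dams —
during the day only (DTC) or around the clock (WDC) — disturb the dams'
activity rhythms compared with cows without contact (NOC). `cowrhythms`
implements the complete analysis chain for that question: data cleaning
and timezone normalization, spectral rhythm detection, two rhythm indices,
and mixed-model inference, plus a synthetic herd generator with known
ground truth so every stage is testable without farm data.

## The two indices

**Degree of functional coupling (DFC).** Activity in a sliding 7-day
window is decomposed with a Lomb-Scargle periodogram (valid under missing
days), powers are tested with the Baluev false-alarm probability (FAP)
bound at P ≤ 0.05, and the DFC is the share of significant spectral power
that sits at *harmonic* periods of the day, 24/n h (24, 12, 8, 6, 4.8,
... 3.4 ... h):

    DFC = sum of significant harmonic power / sum of all significant power

DFC = 1 means all detected rhythmicity is synchronized with the 24-h day;
a window with no significant frequency at all expresses no rhythm, which
is treated as no harmonic rhythm: DFC = 0, flagged degenerate. For
modeling, DFC is median-split into a binary outcome (1 iff DFC = 1, the
empirical median in the data this pipeline targets).

**Diurnality index (DI).** Day is the span between morning-milking end
and evening-milking start, night between evening-milking end and the next
morning-milking start; boundaries follow the 7-day sliding mean of milking
times on the UTC axis (milking drifts with the local clock across
daylight-saving changes). With duration-normalized rates R_d and R_n,

    DI = (R_d − R_n) / (R_d + R_n)  ∈  [−1, 1]

+1 is fully diurnal, −1 fully nocturnal, 0 no preference.

**Inference.** A binomial (logit) GLMM for the binary DFC (fixed: contact
time, estrus, evening milking-start deviation) and a Gaussian LMM for the
1.5-IQR-filtered DI (fixed: contact time, estrus, parity), both with
random intercepts for lactation nested in cow nested in herd and AR(1)
serial correlation across days, fitted with `glmmTMB`.

## Worked example

```r
library(cowrhythms)

# a 7-day, 15-min window of a noiseless rectified 24-h rhythm
t <- seq(0, by = 0.25, length.out = 672)
win <- tibble::tibble(
  cow_id = "demo",
  timestamp = as.POSIXct("2021-09-01", tz = "UTC") + t * 3600,
  motion_index = pmax(0, 10 * cos(2 * pi * t / 24)))
pg <- lomb_scargle(win)
dfc_window(pg)[, 1:4]
#> # A tibble: 1 × 4
#>     dfc n_sig n_sig_harmonic degenerate
#>   <dbl> <int>          <int> <lgl>
#> 1     1     2              2 FALSE
```

The rectified cosine carries significant power at 24 h and its 12-h
harmonic only, so the DFC is exactly 1. A full synthetic-herd run is one
call:

```r
res <- run_pipeline(list(scenario = list(
         n_cows_per_group = c(NOC = 2, DTC = 2, WDC = 2), days = 12),
         dim = list(lo = 59, hi = 66, min_days = 7), fit_models = FALSE),
       out_dir = "scratch/demo", seed = 5)
```

The study-scale analysis (79 cow datasets, 29 days) is the numbered
scripts in `analysis/`; run them in order from the repository root
(`Rscript analysis/01_simulate_herd.R`, ...). They write compact tables
under `results/` and bulky intermediates under `scratch/`. On the default
scenario the Gaussian DI model reports an estrus shift of +0.117 (SE
0.012) with all contact-time contrasts non-significant, and the binomial
DFC model an intercept odds ratio of 3.42 — i.e. rhythms couple to the
24-h day, estrus disrupts them, calf contact does not.

## Input formats

CSV with a header, ISO-8601 local timestamps (UTC offsets recommended):

* activity: `cow_id, timestamp, steps, motion_index` (minute resolution)
* milking schedule: `date, morning_start, morning_end, evening_start,
  evening_end`
* cow metadata: `cow_id, herd, treatment, parity, lactation_number,
  calving_date, estrus_dates` (`;`-separated)

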