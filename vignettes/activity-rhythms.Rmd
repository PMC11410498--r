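---
title: "Methods: activity rhythms, spectral coupling, and diurnality in dairy herds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: activity rhythms, spectral coupling, and diurnality in dairy herds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the models and
rules it implements, the numerical and design choices made where the
problem left them open, what the synthetic herd generator does and does
not emulate, and the limitations a user should keep in mind.

## Data model and cleaning

The pipeline works on minute-resolution activity of dairy cows — step
counts and motion index (MI) from a leg-mounted 3-axis accelerometer —
together with the herd's milking schedule and per-cow metadata (herd,
calf-contact treatment NOC/DTC/WDC, parity, lactation number, calving
date, estrus dates).

All timestamps are converted from barn local time (CET/CEST) to the UTC
timeline before any analysis, so daylight-saving transitions never
duplicate or drop minutes; "days" thereafter mean UTC civil days.
Cleaning applies three rules, each logged per cow and day:

* **Sensor-failure rule.** A day is removed when either channel is zero
  for a run of *strictly* more than 12 h. A zero-run that spans midnight
  disqualifies every day it touches — the conservative reading, since a
  sensor that was dead across midnight was dead on both days.
* **Boundary rule.** The first and last calendar day of each cow's raw
  recording are removed (attach/detach days are partial by nature). This
  rule targets the raw recording edges only: the cleaner marks its output,
  and re-running it is a no-op, which keeps cleaning idempotent.
* **Completeness rule.** Days with fewer than a full day of minutes are
  removed.

Retained data are restricted to days in milk 59–83 (end of early
lactation, clear of calving and weaning effects); cows retaining fewer
than 15 days are flagged out. Finally the minute data are resampled to
15-min bins by summation, anchored at UTC midnight. The bin phase is not
dictated by anything in the data model; midnight anchoring is this
package's documented choice and is configurable. Resampling conserves
daily totals exactly. Only the motion index feeds the rhythm indices;
steps are carried through for completeness.

## Spectral estimation and the DFC

Each cow-day is assigned the 7-day window ending on it (a window labeled
by the day that completes a week of history). Windows retaining fewer
than 5 of 7 days are skipped. The spectral estimator is the classical
Lomb-Scargle periodogram — chosen over the FFT because cleaning leaves
gaps — on the Fourier-style grid k/(7·24 h), k = 1…336 for a complete
window of 672 bins. On this grid every harmonic period 24/n h is an exact
grid point (truncated at the 15-min Nyquist limit of 0.5 h), which makes
harmonic matching exact; off-grid use falls back to a half-grid-step
tolerance. Power is normalized to the fraction of variance explained per
frequency (mean-subtracted input, no further detrending), so it lives in
[0, 1].

Significance uses the Baluev extreme-value upper bound on the false-alarm
probability of a peak searched over the full frequency range, evaluated
per frequency so that the set of "significant frequencies" (FAP ≤ 0.05)
is well defined. Because the bound is an upper bound, thresholding is
slightly conservative; a Monte-Carlo null test in the suite confirms the
exceedance rate stays at or below the nominal level. The bound is defined
for power in [0, 1); the implementation also accepts the noiseless limit
of exactly 1, mapping it to FAP 0, so that ideal test signals pass
through the same code path.

The degree of functional coupling is then

DFC = (significant power at harmonic frequencies) / (all significant power).

Two decisions here are worth flagging. First, the ratio uses *power*
sums, not amplitudes — descriptions of this statistic exist in both
conventions, and power is the quantity the estimator returns natively.
Second, when no frequency is significant, the ratio is 0/0; the package
sets DFC = 0 with a `degenerate` flag, reading "no significant rhythm" as
biologically equivalent to "no harmonic rhythm". The flag is kept so the
two zeros remain distinguishable downstream. For modeling, DFC is
median-split: records equal to 1 (within 1e-9) become 1, everything else
0. The split point is fixed at the maximum because the DFC distribution
this pipeline targets is bimodal with median 1; the empirical median is
reported, with a warning when it is not 1, so the precondition is
checkable on any new dataset.

## Day/night windows, DI, and the milking-deviation covariate

Day is defined as the span between morning and evening milking, night as
the span between evening and next-morning milking; the milking intervals
themselves belong to neither. Because the barn clock follows local time,
milking times jump by an hour on the UTC axis at daylight-saving changes
and the herd adapts over days; day/night boundaries therefore use the
7-day sliding mean of milking start/end centered on the target day. The
centered window is this package's choice — only the milking-deviation
covariate below has an explicitly forward-looking definition — and a
fixture test verifies boundaries drift by at most 60/7 min per day across
a transition instead of jumping 60 min.

The diurnality index contrasts duration-normalized rates, DI =
(R_d − R_n)/(R_d + R_n), because day (~9 h under the default schedule)
and night (~11 h) are unequal; without normalization DI = 0 would not
mean "no preference". The rate-based form is this package's documented
variant. Days where both windows are silent leave DI undefined and are
skipped with a log entry.

The evening milking-start deviation — the covariate for the DFC model —
is the difference in minutes between a day's milking start and the mean
start of that day and the following 6 days (a forward window, exactly as
defined for this covariate), computed on UTC time-of-day.

## Mixed models

Both models use fixed reference levels NOC, diestrus, primiparous.

* Binomial (logit) GLMM for the binary DFC: contact time + estrus +
  evening deviation; random intercepts lactation-in-cow-in-herd; AR(1)
  across days within each cow dataset, expressed as a serially correlated
  latent process on the logit scale — the binomial analogue of AR(1)
  residual covariance. Cow datasets with no outcome variation (all 0 or
  all 1) cannot inform a binomial likelihood and are excluded with a log
  entry.
* Gaussian LMM for DI after 1.5-IQR outlier filtering (type-7
  linear-interpolation quartiles — conventions differ, so the choice is
  pinned and tested against a from-scratch quartile oracle): contact time
  + estrus + parity; same random and serial structure.

Fitting uses `glmmTMB`. Wald 95% CIs on the link scale are exponentiated
into odds ratios for the binomial model. Marginal treatment means average
model predictions over a balanced grid of the other fixed factors with
random effects at zero; for a balanced one-factor design they reduce to
group means, which the suite checks to 1e-6. Fixed-effect terms that are
constant in the supplied data are dropped automatically so degenerate
inputs fail informatively rather than with a rank-deficient design
matrix. Model-selection machinery (information-criterion dredging,
residual-diagnostic simulation) is deliberately out of scope; the two
models above are fitted directly.

A recovery harness (`simulate_model_frame()`) simulates outcomes from
known coefficients with the full random structure at study scale (79 cow
datasets, ≈1,800 cow-days) for calibration tests: with a generating
estrus odds ratio of 0.10 the binomial model recovers the log-odds with
under 25% bias over replicates — some attenuation is expected, as Laplace
approximation in binary mixed models with strong latent variance shrinks
estimates — and the Gaussian model recovers a +0.12 estrus shift within
two standard errors.

## The synthetic herd generator

The generator exists so that every downstream stage has data with known
truth. Per-minute activity is a rectified sum of cosine components at the
harmonic periods (defaults put the largest amplitudes at 3.4 and 4.8 h,
with 24, 12 and 8 h present), multiplied by a day/night envelope that
hits a target diurnal fraction, plus triangular activity bumps of 30 min
width at each milking start, plus white and AR(1) ("red", correlation
time 1.5 h) noise. The ultradian phases are free per cow; the circadian
phase is shared up to small jitter, since cows in one barn are entrained
by the same light and milking cycle. Heterogeneity enters at three
levels: a per-cow lognormal amplitude factor (some cows are strongly
rhythmic, some sit near the detection threshold), a per-cow jitter on the
diurnal fraction (the source of between-cow DI variance), and a per-day
lognormal amplitude factor (a cow's rhythmicity waxes and wanes, so
near-threshold cows yield both significant and rhythm-free weeks — and
the binomial model keeps within-cluster variation). On estrus days
harmonic amplitudes collapse (×0.1), noise inflates (×2), and the
activity share shifts toward the day window (+0.09), reproducing the
signature of estrus: rhythm disruption with daytime restlessness.
Dropout inserts zero-runs of 2–16 h on random days, exercising the
sensor-failure rule.

Reproducibility is strict: one root seed, with per-cow streams derived by
a stable hash of the cow id, so the same scenario and seed are
bit-identical and adding a cow never changes the others. Scenario
defaults emulate the target study's layout: 36/25/18 cows (NOC/DTC/WDC)
in two herds, 29 days starting at 57 days in milk, milking around 05:00
and 16:00 local with 5-min daily jitter. The printed milking times imply
a day window of about 9 h and a night window of about 11 h under the
definitions above; rougher published approximations of those spans are
not jointly achievable with the printed milking times, so the times take
precedence. The default diurnal fraction (0.46) and amplitude scales were
calibrated once so the pipeline's outputs sit in the regime the study
describes — bimodal DFC with median 1, mean DI near +0.1, estrus shifting
DI by about +0.12, modal harmonic period 3.4 h — and are not revisited
per run.

What the generator does *not* emulate: real motion-index noise is neither
Gaussian nor stationary; estrus is a single day with a stylized
signature, not a multi-day episode; there are no season, weather, herd
social or management-event effects; and calves are not simulated, so a
treatment effect can only enter if configured (the defaults encode none —
the study's null result). Consequently, passing tests demonstrate the
*pipeline's* correctness and the models' recovery properties, not
biological claims about real herds. Two quantitative gaps are known and
accepted: the share of windows with *no* significant rhythm is lower than
in the real study (white/red Gaussian noise is easier for Lomb-Scargle
than real behavioral noise), and a single stylized estrus day inside a
7-day window dilutes to a weaker window-level DFC effect than the strong
day-level odds ratio the real data showed; the model-recovery harness,
which injects effects at the outcome level, covers that inferential check
instead.

## Numerical notes and degenerate inputs

* Lomb-Scargle at the Nyquist frequency of an evenly sampled window has a
  vanishing sine regressor; the implementation guards the 0/0 and scores
  that component as zero, where a naive rank-deficient least-squares fit
  would absorb noise.
* Windows with fewer than 8 samples or zero variance are "no rhythm
  evaluable" and feed the degenerate DFC path rather than erroring.
* The acceptance and test problem sizes (windows of 672 bins, herds of a
  few cows for end-to-end checks, 12-replicate calibration loops, a
  1,000-window FAP null) are the package's chosen trade-off between
  statistical resolution and a test suite that runs in minutes.
* All pipeline randomness flows from one seed; rerunning a configuration
  reproduces every table bit-for-bit, which the suite checks by checksum.

## Known limitations

Beyond the generator's realism bounds: the Baluev FAP is an upper bound,
so significant-frequency sets are slightly conservative; the median-split
rule hard-codes the split at DFC = 1 (correct when the median is 1, which
is checked and warned about otherwise); estrus coding accepts any
precomputed per-day flag and does not model multi-day episodes; and with
only two herds the herd-level variance component is weakly identified —
it is retained for structural fidelity, and `glmmTMB` boundary warnings
on it are expected on some datasets.
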