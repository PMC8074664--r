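---
title: "Methods: linking ambient acoustics to everyday heart rate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking ambient acoustics to everyday heart rate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(soundhr)
```

## The measurement chain

Hearing-aid microphones sense the broadband (0–10 kHz) level of the
ambient sound field. The package models the in-device estimators as
operations on a level time series in dB:

* **SPL** — a one-pole low-pass (IIR) smoother
  `y[n] = y[n-1] + α (x[n] − y[n-1])` with `α = 1 − exp(−Δt/τ)` and
  τ = 63 ms. The step response reaches `1 − 1/e` of a level change after
  one τ.
* **Top/bottom trackers** — the same recursion with direction-dependent
  τ. The bottom tracker is a valley detector: it follows the signal down
  with a fast 30 ms release and recovers upward with a slow attack
  (default 3 s, the midpoint of the plausible 1–5 s range; this reading —
  slow upward attack, fast downward release for the valley detector, and
  the mirror image for the peak detector — is the only assignment that
  makes the pair track extrema). Both trackers start at the first SPL
  sample, which guarantees top ≥ bottom pointwise.
* **SML** = top − bottom: the visible modulation depth of the envelope.
  Speech-like signals, whose envelopes carry 2–8 Hz syllabic modulation,
  produce large SML; stationary noise produces small SML.
* **SNR** = SPL − bottom. The defining phrase ("difference between the
  bottom tracker and the immediate SPL") is directionally ambiguous; we
  orient it so that signal above the tracked noise floor is *positive*,
  which is the only orientation consistent with the reported positive
  medians (e.g. ≈ 12.5 dB in Speech). This choice is exposed, not
  hidden: `derive_sml_snr()` documents it.
* **Soundscape** — the in-market classifier is proprietary; the package
  substitutes a documented decision list over (SPL, SML, SNR): Quiet
  below 52 dB SPL, else Speech at SNR ≥ 8 and SML ≥ 15 dB, else
  Speech-in-Noise at SNR ≥ 4 and SML ≥ 10 dB, else Noise. The thresholds
  are configuration, not truths; they are co-calibrated with the envelope
  generator so that synthetic envelopes are classified back to their
  generating class in ≥ 90% of frames.
* **Logging** — one record per 60 s: arithmetic dB means of SPL/SML/SNR
  and the modal class, with ties resolved toward the more complex class
  (Quiet < Speech < Speech-in-Noise < Noise). Complexity-ordered
  tie-breaking is conservative: ambiguity is attributed to the noisier
  environment.

The envelope synthesizer works at 100 Hz (≥ 3 samples per 30 ms release)
and uses duty-cycled syllabic bursts rather than sinusoidal modulation:
the instantaneous SNR of a sinusoidally modulated envelope spends half of
each cycle near zero, which no classifier over momentary values can
assign to a speech class, whereas burst modulation (on at the peak level
for ~55–65% of each 2–4 Hz cycle) matches how speech actually occupies
time. The 63 ms smoother attenuates syllabic-rate modulation
substantially (≈ half at 4 Hz), so generator depths are calibrated on the
*smoothed* output, not the raw envelope.

## Preprocessing

Stages run in a fixed order, each pure and accounted:

1. **Daytime filter**: keep records with clock time in [06:00, 24:00).
   The boundary convention (06:00:00 kept, 05:59:59 dropped) is asserted
   by test.
2. **Alignment**: for each HR log at *t*, average the sound logs in the
   half-open window (t − 300 s, t]. Half-openness prevents a log on the
   boundary from counting in two adjacent windows. A record is emitted
   only when the window holds ≥ 3 of the 5 expected logs (≥ 60% coverage;
   the source description names no minimum — 3 is our choice, exposed in
   `preprocess_config()`).
3. **Percentile filter**: drop records strictly below the 5th or above
   the 95th percentile of heart rate pooled over all participants
   (linear-interpolation quantiles, the same convention everywhere in the
   package). Pooling (not per-participant) follows the description of a
   group-level exclusion.
4. **Participant filter**: drop participants with fewer than 50 aligned
   records (exactly 50 is kept).

The order of stages 3 and 4 is not dictated by the source; we filter
percentiles first (the group percentiles should reflect all plausible
records) and both stages are independently callable.

Movement is estimated from consecutive GPS fixes by the haversine
great-circle distance on a sphere of radius 6 371 000 m, divided by the
fix interval, then averaged over the same half-open 5-minute window.
Exclusion above cycling speed (10 m s⁻¹) applies to the *averaged*
value — a single fast step inside a slow window does not discard the
record. Decile labels come from pooled retained values.

Note a consequence the recovery suite makes visible: on clean synthetic
data the 5/95 percentile filter truncates the response tails and
attenuates fitted slopes by roughly 20%. On real data the filter removes
sensor artifacts (its purpose); on artifact-free simulations it only
biases. The parameter-recovery path therefore stops after alignment,
while `analysis/03_preprocess.R` and `preprocess_pipeline()` run the full
chain.

## The multilevel model

Aligned records are modelled as

y = Xβ + Σₖ Zₖ bₖ + ε

with independent diagonal random-effect blocks bₖ per participant:
an intercept, one slope per standardized continuous predictor, and nested
intercepts for participant×weekday and participant×hour (plus
participant×movement-decile in movement-adjusted fits). Residuals within
each participant-day follow a stationary AR(1) in record order; unequal
time gaps between consecutive records are deliberately ignored (a
discrete-order autoregression, not continuous-time decay). The
random-effect covariance is diagonal because nothing in the source
constrains it and a free covariance would not be identifiable at desk
scale.

Fitting profiles β and σ² out by generalized least squares and maximizes
the remaining likelihood over log variance ratios and atanh(φ) with a
quasi-Newton method (`nlminb`), from the fixed start "every ratio 0.2,
φ = 0", with two deterministic perturbed restarts on failure. One
likelihood evaluation whitens each AR(1) block (an O(n) transform) and
applies the Woodbury identity per participant; because the whitened
cross-products are quadratic in φ with coefficients that do not depend on
the parameters, they are cached once per fit, making an evaluation
O(q³) per participant regardless of n. The structured likelihood is
tested against a dense multivariate-normal oracle to 10⁻⁸, against
`nlme::lme` (corAR1) and `lme4::lmer` on reduced structures, and against
OLS in the zero-variance limit.

Conventions: ML is the default (likelihood-ratio tests against nested
models require it; REML by flag); confidence intervals are Wald
(β ± 1.96 se); LRT degrees of freedom are total parameter-count
differences (fixed + variance + correlation parameters), so acoustic
model vs intercept-only gives df = 6 (3 fixed slopes + 3 random-slope
variances). GVIF is the Fox–Monette determinant ratio on the correlation
matrix of the non-intercept columns, cross-checked against `car::vif`.

**Effect sizes.** Partial R² is the proportional reduction in prediction
error across grouping levels: the observation-level residual sum of
squares (after removing fixed effects and predicted random effects) plus
the sums of squared predicted effects at the weekday and hour levels,
compared between the model of interest and an intercept-only null. The
null keeps the nested intercept structure but *not* the random slopes: a
null with free random slopes absorbs the common slope into its
predictions, which would make the statistic insensitive to exactly the
effects it is meant to measure (its noiseless limit would not reach 1).
Full-model R² replaces the denominator with the total sum of squares.
For log-response fits, dB-scale coefficients back-transform to percent
change per dB via `(exp(β) − 1)·100`.

**Interaction model.** Speech-in-Noise and Noise are collapsed into one
"Noisy" class (their acoustics overlap heavily and they hold the fewest
records); each acoustic slope may differ by class, and with Quiet as
reference each `class:predictor` coefficient *is* the slope contrast
against Quiet, tested by Wald z.

## The synthetic cohort and what it does (not) show

Because the original logs were never deposited, the generator *is* the
study-conditions statement. Defaults: 56 participants × 14 days; sound
logs every 60 s over 06:00–24:00 plus ~5% night-time logs (so the daytime
filter has work); wearable wear-sessions (3/day, ~1.4 h each) whose HR
logs arrive at N(456 s, 168 s) intervals — together ≈ 450 aligned records
per participant (≈ 25 000 per cohort), matching the published cohort
size. Population heart rate 75.60 bpm with the variance split chosen once
as participant 4.0, weekday 1.0, hour 1.5, per-predictor slopes 0.5,
residual 4.5 bpm (marginal AR(1) SD) with φ = 0.5: the published total SD
(6.89 bpm), the printed CI half-widths at n ≈ 25 000 (≈ 0.24 bpm) and the
reported variance-explained magnitudes (≈ 4% fixed, ≈ 56% full) all come
out at the right order with this split, which the source does not itself
decompose. Class-conditional acoustic means/SDs follow the published
medians; hourly occupancy is shaped with Quiet dominant early and late,
Speech peaking in the early evening, and record shares near 35/32/18/15%.

Heart rate is generated *directly from the linear model being fitted* —
the analysis assumes nothing more, so a cardiophysiological simulator
would add realism the models cannot see. One generative configuration
cannot simultaneously carry the acoustic slopes, the soundscape offsets
and the interaction offsets at their published values, because those
numbers come from three separate non-nested fits to one dataset: with
class-conditional acoustics, class offsets load onto acoustic slopes and
vice versa. The generator therefore takes a `scenario` field selecting
which family drives the response, and recovery means
simulate-under-model-M, fit model M — the standard parameter-recovery
design. (Stage 4 of the analysis shows the flip side: fitting the
soundscape model to an acoustic-scenario cohort yields induced,
not configured, offsets.)

GPS tracks mix stationary minutes (Rayleigh jitter, scale 0.085 m s⁻¹,
calibrated so the *windowed* movement median is 0.15 m s⁻¹) with walking
bouts (lognormal around 1.3 m s⁻¹) and ~1% vehicle-speed minutes for the
speed filter to remove.

Passing recovery on these cohorts shows the pipeline is consistent and
unbiased *under its own assumptions*. It does not show robustness to what
real logs contain: irregular wear, device heterogeneity, non-Gaussian HR
artifacts, circadian nonstationarity beyond hour offsets, or classifier
behaviour of the actual proprietary algorithm. The percentile filter
exists for those real-data artifacts, which the generator deliberately
does not emulate.

## Reproducibility and problem sizes

Every stochastic stage takes one seed; participant streams are split by a
stable string hash (order-insensitive, all derived seeds < 2³¹). The test
suite uses small-to-medium cohorts (6×4 shared fixture; 16×12 for the
autocorrelation property; 10×4 × 20 replicates for CI coverage — Wald
coverage of the generative coefficients ≥ 90% is the accepted bar,
allowing mild small-sample anti-conservatism). The acceptance script runs
three full-size cohorts (56×14) per model family; the movement model uses
28×10 cohorts, whose GPS stream is the cost driver, with the slope's
standard error at that size already an order of magnitude below the
effect. Numerical tolerances: likelihood oracle equivalence 10⁻⁸;
optimizer relative tolerance 10⁻¹⁰ on the profiled log-likelihood;
variance ratios bounded in [e⁻²³, e¹²]; recovery asserted within 3
Monte-Carlo standard errors of the mean over seeds.

## Known limitations

* The AR(1) ignores gap lengths between records; long within-day gaps are
  treated like adjacent records.
* `effective_sampling_frequency()` averages over participant-day-hour
  cells with at least one record; cells that are empty because devices
  were off do not enter the denominator, so the statistic reads "records
  per hour while wearing", which is higher than a calendar-hour average.
* Wald intervals and z-tests everywhere; no small-sample df correction
  (the intended regimes have thousands of records).
* The classifier stand-in reproduces class geometry, not the proprietary
  decision surface; absolute occupancy shares under the envelope mode
  depend on its thresholds.
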