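---
title: "From respirometry traces to repeatable metabolic phenotypes: the anuranRMR methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From respirometry traces to repeatable metabolic phenotypes: the anuranRMR methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anuranRMR)
```

## The scientific problem

Behavioral-energetics studies of calling frogs ask whether maintenance
metabolism — resting metabolic rate, RMR — constrains or fuels an
energetically expensive sexual display. The three competing energy
management models predict a negative (allocation), positive (performance)
or absent (independent) association between RMR and display output.
Answering the question requires three measurement chains:

1. **Respirometry**: multiplexed push-mode flow-through respirometry of
   small (~5 g) ectotherms at 25°C, reduced to oxygen consumption
   ($\dot{V}_{O_2}$, ml O$_2$ h$^{-1}$) and summarized as a trial RMR.
2. **Bioacoustics**: advertisement-call recordings reduced to five
   characteristics — call duration, pulse number, dominant frequency,
   call rate and call effort.
3. **Biostatistics**: mixed models linking the two, adjusted repeatability
   of RMR, and the decay of within-individual consistency over the season.

anuranRMR implements all three chains plus a synthetic-data generator with
known ground truth, so that every stage is testable without field data.

## Respirometry reduction

A raw trace carries O$_2$ (%), CO$_2$ (%), water vapor pressure (WVP, kPa),
barometric pressure (BP, kPa), flow rate (FR, ml min$^{-1}$) and the active
chamber id; channel 0 is the empty baseline chamber. The reduction chain is:

1. **Lag alignment** (`correct_lag`). In a serial analyzer train the O$_2$
   and CO$_2$ cells respond to a chamber switch later than the WVP cell.
   The integer-sample lag is found by maximizing the normalized
   cross-correlation of rectified first differences, which concentrate at
   switch transients. If the best alignment is still poor (normalized score
   < 0.3 — no overlapping transients within the search bound), the channel
   is left unshifted and flagged. Commercial acquisition software does this
   semi-automatically; our criterion is deterministic and auditable.
2. **Baseline drift correction** (`baseline_correct`). A drift curve is
   interpolated through the per-baseline-segment medians of each gas
   channel (linear by default; a natural spline is available when ≥4
   baseline segments exist) and the signal is referenced to it. The O$_2$
   deflection is negated and divided by 100, so $\Delta O_2 \ge 0$ during
   consumption; CO$_2$ is divided by 100 with its native sign. Animal
   segments outside the span of baseline nodes are flagged as extrapolated.
3. **Flow correction** (`correct_flow`): $FR_d = FR \,(BP - WVP)/BP$.
   The mass-flow meter meters dry air upstream of the rehydration stage, so
   the flow carrying the measured gas fractions is diluted by water vapor.
4. **Oxygen consumption** (`compute_vo2`): with excurrent air scrubbed of
   water and CO$_2$ before the O$_2$ cell,
   $\dot{V}_{O_2} = 60\, FR_d\, \Delta O_2 / (1 - Fe_{O_2})$, where
   $Fe_{O_2} = Fi_{O_2} - \Delta O_2$; the factor 60 converts ml min$^{-1}$
   to ml h$^{-1}$.

### Numerical and design choices

* `fio2_ref` defaults to 0.2095 (atmospheric). After flat-baselining,
  $\Delta O_2$ is referenced to the baseline, so `fio2_ref` enters only the
  $(1 - Fe_{O_2})$ denominator; a ±0.002 error moves $\dot{V}_{O_2}$ by
  about 0.3%, far below trace noise.
* `washout_s` defaults to 60 s: samples discarded after each channel switch
  while chamber air reaches the analyzers. Multiplexed systems require
  this even though reduction descriptions rarely mention it; `washout_s = 0`
  reproduces a literal no-trimming reduction.
* The logger sampling rate is configurable (default 1 Hz, the field
  standard for this class of hardware); all windows are specified in
  seconds and converted to samples internally.
* Whether $\Delta O_2$ is referenced to `fio2_ref` or to the corrected
  baseline is moot after flat-baselining: the two coincide by construction.

## RMR extraction

A trial is three 15-min repetitions per animal. Extraction is:

1. **Activity screening** (`screen_activity`). Field practice is visual
   inspection for "sudden changes"; we automate it: the repetition is
   smoothed (11 s window), and discarded when the largest absolute first
   difference exceeds 6 times the MAD of those differences (MAD scaled to
   the SD under Gaussian noise). Under pure analyzer noise the statistic
   sits near 3–4; injected activity bursts (×3 amplitude) push it above 50.
   The threshold is overridable, and the per-repetition statistic is
   recorded for interactive review.
2. **Two-stage window search** (`find_candidate`): the 450-s interval with
   the lowest $\dot{V}_{O_2}$ SD, then the 60-s interval inside it with the
   lowest mean. Ties break to the earliest window; stride is one sample.
   Both choices are unstated in standard descriptions of the procedure and
   are documented here as conventions.
3. **Trial RMR** (`extract_trial_rmr`): the minimum candidate mean across
   surviving repetitions. A trial with no usable repetition is marked
   unusable rather than erroring, mirroring removal of whole trials.

Because RMR is a minimum statistic it is downward-biased under noise; the
bias is zero on noiseless traces and grows with the noise SD (this is
asserted in the test suite). At the default noise level (VO$_2$-equivalent
SD ≈ 0.02 ml h$^{-1}$) the bias is below 1% of a typical 0.9 ml h$^{-1}$
signal.

We treat the "relatively stable areas" pre-selection and the 450-s search
as coincident — i.e. the stability search *is* the stable-area selection.

## Call characteristics

From an event table (onset, offset, pulse count, dominant frequency per
call), `recording_features` computes per-recording means of the five
characteristics. Call rate is the reciprocal onset-to-onset interval
(final call excluded); call effort is duration × rate per call, its mean
taken over the calls with a defined rate. Inter-observer reliability
(`interobserver_reliability`) is the Pearson correlation plus OLS slope of
observer B on A, pooled per characteristic across recordings (a
per-recording breakdown is a trivial split, but the pooled figure is the
one comparable across studies).

The optional audio path (`extract_from_audio`) segments calls by
hysteresis thresholding of a smoothed amplitude envelope, counts pulses as
hysteresis crossings of a finer envelope at half the call's peak, and takes
the dominant frequency from a Welch periodogram (2048-sample Hann windows,
50% overlap). It is a bespoke re-implementation of measurements usually
made interactively in a spectrogram GUI and is documented as
non-identical to any particular tool. It is exact on synthesized pulsatile
calls up to 80 pulses s$^{-1}$ at 20 dB SNR, which covers fast-pulsed
treefrog calls; real chorus recordings with overlapping callers are out of
scope.

## Statistical battery

All mixed models are Gaussian random-intercept models fit by REML through
lme4. Five call-trait models share the fixed structure
`trait ~ RMR + temperature + calendar day + mass + year` (year categorical,
reference 2023) with an individual random intercept. RMR enters
*uncorrected* for body mass: the hypotheses concern gross maintenance
expenditure, and mass is a separate covariate. The RMR model is
`RMR ~ calendar day + mass + year`, with optional centered-quadratic-day
and log10–log10 variants.

Fixed-effect p-values use Wald *t* with residual degrees of freedom
$n - k$. This is simpler than Satterthwaite or Kenward–Roger
approximations and can differ from them in the third decimal at these
sample sizes; it is documented as a deliberate, minor divergence.

**Repeatability** (`repeatability`) is the paper-defined computation and is
implemented here rather than delegated: $R = V_{ind}/(V_{ind}+V_{res})$
from the covariate-adjusted REML fit; a percentile CI from a parametric
bootstrap (simulate responses from the fitted model, refit, recompute R;
seed mandatory; default 1000 replicates); and a likelihood-ratio test of
$V_{ind}=0$ using ML fits referred to the boundary mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$.

**Consistency** (`consistency_analysis`) regresses the absolute first-to-
last change in RMR on the days between, one point per individual with
repeated within-year trials (temporal first and last, maximizing the
interval). Cross-year pairs are excluded; an individual whose three
captures span two years contributes only its within-year pair. The
day-residualized variant first residualizes RMR on calendar day across all
trials, asking whether consistency decays beyond the shared seasonal
decline. When the days-between regressor is constant it is aliased and the
slope is reported as 0 with no test.

## The synthetic world

The generator is a *stated world*, not a tuning dial; its defaults are
anchored to the observed scale of a treefrog field study and are not moved
to make tests pass.

* **Cohort** (`simulate_cohort`): 100 individuals, mass ~ N(5.1, 0.8²) g,
  trial RMR = 1.85 + 0.18·mass − 0.01·day − 0.24·[year 2] + b + ε with
  $b \sim N(0, 0.02)$, $\varepsilon \sim N(0, 0.03)$ — adjusted
  repeatability 0.02/0.05 = 0.4 — days 130–200, recapture fractions
  0.71/0.21/0.08 for 1/2/3 trials, gaps 3–45 days. The intercept is set so
  the realized cohort mean is ≈0.92 ml h$^{-1}$ (SD ≈ 0.38) under the
  *realized* trial-day distribution, which sits later than the season
  midpoint because repeat captures accumulate late-season trials.
* **Traces** (`simulate_trace`): the exact inverse of the reduction
  equations plus linear analyzer drift (−0.01 %/h O$_2$), white noise
  (O$_2$ SD 2.7×10⁻⁴ %, i.e. a VO$_2$-equivalent SD of ~0.02 ml h$^{-1}$
  at 100 ml min$^{-1}$), optional injected gas-channel lag, and labeled
  multiplicative activity bursts (×3 for 120 s, 8% of repetitions) — a
  crude stand-in for real activity, which has no accepted model. Chamber
  air on animal channels carries slightly higher WVP (+0.25 kPa), which
  both reflects a humid occupied chamber and provides the switch
  transients that lag estimation needs.
* **Calls** (`simulate_calls`): each trait follows a mixed-effects
  generative model with individual intercepts, recording deviations and
  call-level noise; fixed effects put a typical call at ~0.6 s, ~30
  pulses, ~2.4 kHz, ~0.18 calls s$^{-1}$ at 21.7°C, with duration falling
  0.03 s/°C, rate rising 0.010 s$^{-1}$/°C and dominant frequency falling
  ~64 Hz/g. (Published tables of such models sometimes print the rate–
  temperature row with inconsistent sign between estimate and *t*; the
  generator uses the physically coherent positive slope.) The RMR effect
  on every trait defaults to 0 — the null world. Optional audio synthesis
  renders each call as a raised-cosine pulse train at a stated SNR.

What a green test does **not** establish: the generator has Gaussian
noise, linear drift, step-like activity and no chamber washout kinetics,
no social-context variation in calling, and no mass–RMR allometry beyond
the linear slope. Field data violate all of these to some degree; the
tests establish correctness of the *computation*, not field validity of
the defaults.

Two deliberate world adjustments in specific checks (both visible in the
test code, neither a tolerance change): the repeatability-recovery world
zeroes the year offset, because a year shift not conditioned on by the
mass+day-adjusted estimator would add ≈0.014 to the among-individual
variance and raise the true adjusted R to ≈0.53 — the check's premise is a
world whose true adjusted R is exactly 0.4. The consistency-contrast world
densifies recaptures (150 individuals, 40/40/20) so the first/last
regression has ~90 pairs; with the field scheme's ~29 pairs the raw-slope
test is significant in only ~3 of 4 seeds, which would make a qualitative
contrast test flaky rather than informative.

## Orchestration

`run_pipeline` ties the stages together from a YAML-serializable config
(seed mandatory), writes the stage outputs as CSV/JSON, and records a
manifest with the package version, a config hash and per-output checksums;
identical configs give identical checksums. The `anuranRMR` CLI
(`inst/cli/anuranRMR`) exposes `simulate | reduce | rmr | calls | analyze |
run`. Errors abort with the failing stage named and an `INCOMPLETE` marker
left in the output directory.

## Known limitations

* No $\dot{V}_{CO_2}$/respiratory-quotient analysis: CO$_2$ is carried
  through reduction as a QC channel only.
* No parsing of proprietary binary acquisition formats; the native format
  is the documented CSV dialect with a column-mapping option.
* Activity screening is calibrated on the generator's step bursts; real
  activity may be subtler and should be reviewed via the exported
  per-repetition statistics.
* Cross-year repeatability is deliberately out of scope (insufficient
  cross-year data in the motivating design).
* The audio path assumes a single caller well above the noise floor.
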