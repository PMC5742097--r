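---
title: "Audience-response metrics from EEG and eye gaze: models, parameters, design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Audience-response metrics from EEG and eye gaze}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trailermetrics)
```

## The problem

Pilot audiences watching a movie trailer produce two streams of objective
data besides their stated preferences: where they look, sampled at 60 Hz
by an eye tracker, and how their cortical activity evolves, sampled by a
multi-channel EEG.  `trailermetrics` condenses each stream into a single
per-trailer number designed to capture one property of the stimulus:

* **attentional asynchrony** — how *inconsistently* the trailer guides the
  group's overt attention over time;
* **cognitive congruency** — how *reproducibly* the trailer modulates
  band-limited EEG power when the same person watches it a second time.

Both are then related to a box-office key performance indicator (weekend
revenue divided by production budget) through a small regression harness.
This vignette explains the two models, the parameters that matter, the
numerical choices, and what the synthetic-data generators do and do not
emulate.

## EEG conditioning

`preprocess_continuous()` fixes the conditioning chain as *downsample →
high-pass → notch → average reference*:

* resampling to 256 samples/s accepts only integer decimation factors and
  low-passes at 80% of the new Nyquist (8th-order Butterworth) first;
  upsampling is refused rather than interpolated;
* the DC/drift high-pass is a 4th-order Butterworth at 1.5 Hz;
* power-line interference is removed with 2nd-order Butterworth band-stops
  at 50 and 100 Hz, bandwidth `f0/Q` with `Q = 30`;
* every sample is re-referenced to the instantaneous channel average.

The method description this package implements names the cutoffs and the
order of the steps but not the filter realizations; the orders and Q above
are conventional EEG practice and are arguments, not constants.  All
filters run forward–backward (`signal::filtfilt`), so the chain is
zero-phase — epochs are later compared across viewings sample by sample,
and any group delay would masquerade as asynchrony.  Forward–backward
filtering leaves edge transients; the first and last second of the
continuous output should not be interpreted, which is harmless because
epochs carry ±2 s of padding (`epoch_signal()`, baseline window
`[-2000, 0)` ms removed per channel; windows are half-open and sample
indices 0-based throughout).

## Time–frequency power

`morlet_power()` convolves each channel with complex Morlet kernels on the
half-Hz grid 1–80 Hz (159 bins).  Two choices are not dictated by the
method description:

* **wavelet width** — fixed 7 cycles at every frequency, the common EEG
  default; narrower wavelets would trade frequency for time resolution;
* **the 8 samples/s power series** — "temporal resolution of 8 Hz" is
  implemented as the mean of squared coefficient magnitudes inside
  consecutive non-overlapping 125 ms bins, the simplest reduction
  consistent with that statement.

Kernels are normalized so a unit-amplitude sinusoid at the analysis
frequency yields power ≈ 1 µV²; power is linear (not log) because the
congruency step is defined on covariances of power and the method
description is silent about any transform.  Power samples whose wavelet
support crosses the epoch edge are kept: the ±2 s padding covers the
support of every band ≥ 14 Hz, the only bands used downstream.

The band lists deserve a note: the source material prints three mutually
inconsistent beta lists (one of them "14–8 Hz") in different sections.
The defaults here are beta {14–16, 16–18, 18–20} and gamma
{40–48, 52–60, 60–70, 52–70} Hz, the only reading consistent across
sections; band edges are inclusive on the grid (so 40–48 Hz averages 17
bins), and every list is configurable.

## Cognitive congruency

For subject *s* and viewing *i*, `X(i,s)` is the D × T band-power matrix.
`viewing_covariances()` forms

\[ R_{11} = \tfrac{1}{|S|T}\sum_s \tilde X_{1,s}\tilde X_{1,s}^\top,\quad
   R_{22} \text{ analogously},\quad
   R_{12} = \mathrm{sym}\big(\tfrac{1}{|S|T}\sum_s \tilde X_{1,s}\tilde X_{2,s}^\top\big), \]

and `solve_congruency()` returns the largest eigenvalue of
\(\lambda (R_{11}+R_{22}+\gamma I) w = R_{12} w\).  Four decisions were
genuinely open:

* **centering** — each channel's power series is mean-centered within its
  epoch (the tilde above) before the products.  "Covariance" suggests it,
  and without centering the large common offset of power (power is
  non-negative) dominates every eigenvalue;
* **symmetrization** — `R12` is stored as `(R12 + R12')/2`.  The Rayleigh
  quotient only sees the symmetric part, and symmetrizing makes the
  problem symmetric-definite so all eigenvalues are real;
* **shrinkage** — D channels with short T can make `R11 + R22` singular;
  the default ridge is `γ = 1e-6 · trace(R11+R22)/D`, scale-free and small
  enough not to move λ at test sizes.  `γ = 0` disables it, which is what
  the analytic facts use (identical viewings give λ = 1/2 *exactly* only
  at γ = 0);
* **one component** — the metric is the top eigenvalue only; the full
  spectrum is returned for diagnostics but unused, and λ is a normalized
  quotient, so no correction for trailer duration is applied.

The solver reduces the problem by Cholesky (`L L' = R11+R22+γI`,
eigendecomposition of `L⁻¹ R12 L⁻ᵀ`), which keeps everything symmetric.
For covariances built from actual paired data, `|λ| ≤ 1/2` by
Cauchy–Schwarz; this bound is asserted on randomized instances in the
tests.  The forward model `a = R̄w/(w'R̄w)` (with `R̄ = (R11+R22)/2` and
`w` normalized to unit length first, making `a` exactly invariant to
rescaling of the filter) maps the extracted filter back to a scalp
pattern.

Note one subtlety the raw-signal end-to-end test makes explicit: when a
source is mixed into *signals* through weights `m`, its *power* appears in
channels through `m²`; topography recovery from band power therefore
targets the squared mixing pattern.

## Attentional asynchrony

Traces (participant × viewing, pooled or restricted to one viewing) are
segmented into 250 ms windows with 50 ms hop — 15 samples and hop 3 at
60 Hz, `floor((n-15)/3)+1` windows.  For each window the pairwise
Euclidean pixel distances between time-matched samples of distinct traces
are collected; no within-trace or cross-time pairs, because the quantity
of interest is instantaneous inter-viewer dispersion.

The permutation null shuffles the *window order* of every trace
independently, which preserves within-window gaze structure but destroys
alignment across viewers; its central 90% interval `[q05, q95]` is
estimated from `n_draws = 1000` permutations with linear-interpolation
quantiles.  The main interpretive ambiguity in the source description is
whether a *divergent* window has distances *inside* or *outside* that
interval.  This package implements the **inside** reading: the null
describes temporally misaligned viewing, so distances consistent with the
null mean the window shows no synchronization, whereas genuinely
synchronized windows sit *below* `q05`.  That reading matches the
metric's name (high = asynchronous), its two limits (i.i.d. gaze scores
≈ 1, a single shared path scores ≈ 0), and its negative association with
performance.  The opposite reading is available via `rule = "outside"`.

Remaining rules, all explicit arguments: divergence threshold
`frac = 0.30` on the distance share, with the boundary (share exactly
30%) counting as divergent; a trace enters a window only if ≥ 50% of its
window samples are valid; windows with fewer than two usable traces are
unclassifiable and excluded from both numerator and denominator; a
degenerate null (zero width) classifies every window as non-divergent.
Invalid gaze rows are flagged and carried, never dropped, and carry no
information — tests overwrite their coordinates with garbage and assert
the score is unchanged.

One implementation note: pooling *every* distance from *every*
permutation draw is O(n_draws · windows · pairs · 15) and can reach 10⁸
values at realistic sizes.  The estimator therefore evaluates, per draw, a
random subset of window slots chosen so the total pool stays near
`max_pool` (default 2 × 10⁵).  The quantiles are Monte-Carlo estimates in
either case; the cap only widens their Monte-Carlo error, which the
Monte-Carlo-oracle test bounds at a few pixels.

## Behavioral metrics, KPI, outlier rule

`behavioral_metrics()` pools across participants and both viewings: mean
liking (LM) and the yes-fractions of willingness-to-watch (WTW) and
willingness-to-refer (WTR).  Liking is accepted on 0–10: the instrument
is nominally 1–10 but observed responses include 0, so the wider range is
the one that admits the data.  The KPI is revenue/budget; the packaged
15-movie table stores the ratios directly.

The outlier rule is formalized as a one-sided leave-one-out z-score:
movie *i* is excluded iff `(kpi_i − mean(kpi_-i)) / sd(kpi_-i) ≥ 4`
(sample SD; zero spread among the others with a deviating value also
excludes).  On the packaged premiere column this excludes exactly the
first movie at z = 4.38, and the exclusion propagates to all weekend
regressions, which therefore run on n = 14.

## Regression harness

`fit_linear_model()` is OLS with intercept; its result carries the
identities `r2_adj = 1-(1-r2)(n-1)/(n-k-1)` and
`F = (r2/k)/((1-r2)/(n-k-1))` to 1e-10, asserted on every fit in the
tests.  The bootstrap SE on R² is case resampling over movies (default
`B = 2000`, seeded); resamples with a constant predictor are redrawn and
counted.  `weekend_sweep()` fits the seven default models — per-viewing
asynchrony, four gamma-band congruency variants, and the combined
bivariate model — against the premiere and eight weekend KPIs.  Two open
choices: the FDR family is the nine outcomes within one model row (the
source says only that regression statistics were corrected), and the
combined model pairs first-viewing asynchrony with the 52–70 Hz
congruency band (the source names 60–70 Hz in one section and uses 52–70
elsewhere; 52–70 is the default and the band is an argument).

## What the generators emulate

`sim_config()` defaults to desk scale — 8 subjects, 6 trailers of 30 s,
8 channels — against the real design's 27 participants and 15 trailers,
keeping the full suite a two-minute run while preserving the paired
two-viewing structure.

* `simulate_eeg_study()` plants one spatially fixed component per trailer:
  a smooth standardized AR(1) course shared between a subject's two
  viewings, mixed through a random unit topography at `sqrt(snr)`, plus
  unit channel noise.  The population eigenvalue is then
  `snr/(2 snr + 2)`, which the recovery tests confirm across an SNR grid.
  The `"raw"` level amplitude-modulates a 61 Hz carrier instead and is
  pushed through the full conditioning → Morlet → band → congruency chain
  in one test.  Not emulated: volume conduction, 1/f spectra, artifacts,
  inter-subject topography variability — so passing tests demonstrate
  correct recovery of the planted structure, not robustness to real EEG.
* `simulate_gaze_study()` mixes a shared smooth attractor path (sum of
  low-frequency sinusoids) with an independent wander per trace at weight
  ρ, plus 5 px jitter and 2% invalid samples.  ρ = 1 and ρ = 0 reproduce
  the two asynchrony limits; the score is monotone non-increasing in ρ
  across seeds.  Not emulated: saccade/fixation dynamics, blinks with
  temporal structure, calibration drift.
* `simulate_behavior_kpi()` couples the premiere KPI linearly to a
  ground-truth metric (defaults: intercept 0.35, slope 0.8, noise SD
  0.08 — chosen to keep simulated KPIs in the packaged table's range) and
  decays weekends geometrically (factor 0.45, matching the premiere →
  weekend-1 ratio of the packaged table) with lognormal noise.  Liking
  follows the scaled metric with a participant random effect;
  WTW/WTR are Bernoulli in the liking.

All randomness derives from one master seed through named substreams
(`derive_seed()`), so each generator is reproducible in isolation.

## Problem sizes and checks

The test-suite sizes are the package's own choices for a desk-scale run:
recovery checks use 4 channels, 4–6 subjects and 60 s of band power per
trailer (20 seeds × 5 SNR points); asynchrony checks use 8 traces of
20 s, 150–300 permutation draws (20 seeds × 5 synchrony points); the
bound `|λ| ≤ 1/2` is asserted on 1000 randomized covariance sets; the
grid-search oracle compares the eigensolver against 10⁵ unit-circle
directions at D = 2; KPI slope coverage runs 200 simulated studies of 60
trailers with 400-resample percentile intervals.  `scripts/acceptance.R`
re-runs the same checks from scratch against the installed package and
writes the numbers as JSON.

## Known limitations

* The headline regression results of the study this design follows (R²
  values per model and weekend) are not recomputable: the underlying
  recordings were never deposited, and per-trailer metric values are not
  printed.  What is recomputable — the outlier z, the F/adjusted-R²
  identities, and every structural property of the metrics — is.
* The EDF/BDF reader covers the common single-rate subset of the formats
  and does not parse EDF+ annotation channels; event markers travel in
  the matrix_csv sidecar.
* The permutation-null quantiles are Monte-Carlo estimates; with the
  default `max_pool` their error is a few pixels, negligible against the
  30% share rule in every tested regime, but extremely tight decision
  margins would warrant raising `max_pool` and `n_draws`.
* Screen geometry defaults to 1024 × 768 (the "1024 × 758" in the source
  is treated as a typo) and is configurable.
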