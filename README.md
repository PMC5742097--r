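# trailermetrics

Neurophysiological audience-response metrics for video stimuli, and a
regression harness relating them to box-office performance.

When a group of viewers watches the same movie trailer twice while EEG and
eye-gaze are recorded, two things can be quantified: how consistently the
trailer *guides overt attention* across viewers, and how reproducibly it
*modulates band-limited cortical power* across the two viewings.  Both
quantities turn out to carry information about how the wider population
responds to the film.  `trailermetrics` implements the two metrics, the
signal processing around them, the stated-preference and box-office
summaries, and the model-by-weekend regression sweep, plus synthetic-data
generators so the entire pipeline is testable without any recordings.

## The two metrics

**Attentional asynchrony** (eye gaze).  Gaze traces of all viewers are cut
into 250 ms sliding windows with a 50 ms hop (80% overlap).  For each
window the pairwise Euclidean distances between time-matched gaze points of
all viewers are compared with a permutation null obtained by shuffling the
window order of every trace independently (destroying temporal alignment
across participants and viewings).  A window is *divergent* when at least
30% of its distances fall inside the central 90% interval of that null —
i.e. when inter-viewer dispersion is indistinguishable from misaligned
viewing.  The metric is the fraction of divergent windows: 0 means gaze was
tightly guided throughout the trailer, 1 means it was not guided at all.

**Cognitive congruency** (EEG band power).  Each viewer's epoch is
decomposed with complex Morlet wavelets (half-Hz grid, 1–80 Hz),
instantaneous power is averaged into a frequency band (beta and gamma bands
by default) giving matrices `X(i,s) ∈ R^{D×T}` for viewing `i` of subject
`s`.  With subject-aggregated covariances

    R11 = 1/(|S|T) Σ_s X(1,s) X(1,s)',   R22 analogously,
    R12 = sym( 1/(|S|T) Σ_s X(1,s) X(2,s)' ),

the metric is the largest eigenvalue λ of the generalized eigenvalue
problem `λ (R11 + R22) w = R12 w`, i.e. the maximum over spatial filters
`w` of `w'R12 w / (w'(R11+R22)w)`.  λ is bounded by 1/2, attained exactly
when both viewings produce identical filtered power; the corresponding
forward-model topography `a = R̄w / (w'R̄w)` shows where on the scalp the
reproducible component lives.

Both metrics feed a per-trailer study table together with stated-preference
scores (mean liking, willingness-to-watch and willingness-to-refer
fractions) and the sales-performance KPI (weekend revenue / production
budget, premiere plus eight weekends; a 15-movie KPI table ships with the
package).  A leave-one-out z ≥ 4 rule excludes KPI outliers, and
`weekend_sweep()` fits each of seven models against the nine outcomes with
bootstrap standard errors on R² and Benjamini–Hochberg correction across
the weekends within each model.

## Worked example

```r
library(trailermetrics)

# packaged premiere KPIs: the leave-one-out rule excludes exactly one movie
kpi  <- movie_kpi()
mask <- flag_outlier(kpi$premiere)
which(mask)            # 1
attr(mask, "z")[1]     # 4.38

# plant a weak and a strong cross-viewing EEG component, then recover them
cfg <- sim_config(n_subjects = 6, n_trailers = 2, trailer_dur_s = 60,
                  n_channels = 4, snr_congruency = c(0.5, 4), seed = 2024)
eeg <- simulate_eeg_study(cfg)
for (tr in eeg) print(cognitive_congruency(tr$subjects))
#> <congruency_result> lambda = 0.1674 (band ?, trailer NA)
#> <congruency_result> lambda = 0.3990 (band ?, trailer NA)

# unguided vs tightly guided gaze
gaze <- simulate_gaze_study(sim_config(n_subjects = 4, n_trailers = 2,
        trailer_dur_s = 20, gaze_sync = c(0.1, 0.95), seed = 2024))
for (tr in 1:2) print(attentional_asynchrony(gaze, trailer = tr,
                                             n_draws = 300, seed = 11))
#> <attentional_asynchrony> score = 1.000 over 396 windows (divergent=396)
#> <attentional_asynchrony> score = 0.000 over 396 windows (non_divergent=396)
```

λ rises with the planted signal-to-noise ratio (its population value is
`snr/(2 snr + 2)`, so 0.167 and 0.4 are the expected readings), and the
asynchrony score falls from 1 to 0 as the shared-attractor weight of the
gaze simulation approaches 1.

A command-line front end wrapping the same functions is installed as
`exec/trailermetrics` (subcommands `simulate`, `preprocess`, `asynchrony`,
`congruency`, `behavioral`, `kpi`, `predict`; all accept `--config` and
`--seed`).

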