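---
title: "Methods: simulating and decoding same-limb motor imagery EEG"
author: "mibci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and decoding same-limb motor imagery EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mibci)
```

## The problem

Motor imagery of different movements of the *same* limb — a hand grasp, an
elbow movement, a goal-directed elbow movement — produces subtle, partly
overlapping modulations of the sensorimotor rhythms recorded over a small
patch of cortex. A brain–computer interface (BCI) that distinguishes them
must (i) detect event-related desynchronization (ERD) of the mu (~8–12 Hz)
and beta (~14–26 Hz) rhythms relative to a pre-cue baseline, (ii) exploit
the slightly different scalp topographies of the tasks, and (iii) turn
single 2-second epochs into class decisions.

`mibci` implements this full analysis chain and, because raw recordings of
this kind are rarely shareable, pairs it with a seeded synthetic-data
generator that reproduces the paradigm's structure: cues of 3 s, rest
intervals drawn uniformly from 5–7 s, sessions of balanced randomized
trials, acquisition at 1000 Hz on a 20-channel vertex-referenced montage.
Every downstream stage is therefore testable against *known planted
effects*.

## The synthetic generator

The signal model is a sum of three parts, per channel and time point:

* **Background**: Gaussian noise with an AR(1) low-pass shape (knee at
  ~20 Hz, shape roughly invariant to the sampling rate), spatially mixed
  across channels (`diag + 0.3·random`, rows normalized) and scaled to
  `noise_scale` µV RMS (default 10 µV).
* **Mu and beta sources**: band-filtered white noise (8–11 Hz and
  14–18 Hz, unit RMS, default amplitudes 6 and 4 µV at a unit-gain
  channel). Narrowband *noise* rather than pure sinusoids is essential:
  sinusoidal sources make trial covariances rank-deficient and CSP
  degenerate, and give log-variance features no realistic trial-to-trial
  spread.
* **Modulation**: each imagery class owns one mu and one beta source
  projected through a per-class topography (gains in [0, 1] per channel).
  During that class's trials the source amplitude ramps down 0.7 s after
  the cue (reaction/decision latency) to `sqrt(1 - depth)`, holds until
  cue end, and returns to baseline over `recovery_s`. The beta source may
  rebound above baseline (ERS, amplitude `sqrt(1 + gain)`) before
  settling; the goal-directed class plants no rebound and recovers more
  slowly (1.4 s vs 1.0 s). REST plants nothing.

Default class topographies are modeling choices, not measurements:
MI-GRASP is focal over contralateral motor cortex (C3), MI-ELBOW is
broader (C3 + FC3), MI-ELBOW-GOAL adds a posterior parietal component
(Pz). Default ERD depths (0.5 / 0.45 / 0.6 in mu power) keep the
goal-directed task's ERD deepest; no published effect sizes exist for
these depths, so they were fixed once for testability and are documented
as such.

All randomness flows from one root seed through named sub-streams
(`sub_seed`): trial order, inter-trial intervals, background noise,
spatial mixing, and each class's sources are independently reproducible.

**What the generator does not emulate**: volume-conduction head geometry,
ocular/muscle artifacts, electrode drift, inter-session nonstationarity,
and 1/f detail beyond the AR(1) approximation. Passing tests on this data
show the *pipeline* is correct and sensitive at a known SNR; they do not
certify performance on real EEG.

### Oracles and dilution

`planted_effect_oracle()` reads the planted percent power change straight
off the class specification (e.g. −50% for a mu ERD depth of 0.5) —
*source level*, no synthesis. At a scalp channel the change is smaller,
because band-limited background noise and the other classes' baseline
sources add power that does not modulate. `dilution_factor()` measures
the modulated source's share of baseline band power at a channel from
short component-wise syntheses, so tests can compare a measured ERD
against `dilution × planted` without circularity through the analysis
pipeline.

## Preprocessing

Data are downsampled to 250 Hz (8th-order Butterworth anti-alias low-pass
at 0.4 × target rate, zero-phase, then integer decimation) and band-pass
filtered to 6–35 Hz on the continuous signal before epoching. The broad
filter is a 6th-order zero-phase Butterworth: a 4th-order design leaves a
50 Hz mains tone attenuated by only ~37 dB after both passes, short of
the 40 dB this package guarantees; 6th order gives ~54 dB with unity
(±1 dB) passband gain. Narrow per-band filters downstream (7–30 Hz and
the filter-bank bands) use the conventional 4th order — their job is
band selection, not interference rejection. Filtering precedes epoching
so that epochs never contain filter edge transients; the generator
guarantees at least 2 s of signal before the first cue.

Epochs are cut 1–3 s after each cue over the half-open sample window
`[floor((onset+start)·fs), … + round((end−start)·fs))` — 500 samples at
250 Hz. Flooring (rather than rounding) the start index is arbitrary but
fixed, so epoch boundaries are bit-stable across runs.

## Feature extraction

Three extractors, all yielding log-variance features of 2 s epochs:

* **CSP** (7–30 Hz, 6 features): for classes A and B, per-trial spatial
  covariances are trace-normalized (equalizing trial energy — standard
  practice) and averaged per class. The generalized eigenproblem
  `C_A w = λ (C_A + C_B) w` is solved by whitening the composite
  covariance; λ ∈ [0, 1] is the fraction of composite variance explained
  by class A. The 3 filters with largest λ and the 3 with smallest are
  kept. Every filter is rescaled to satisfy `wᵀ(C_A + C_B)w = 1` exactly;
  a diagonal ridge of `1e-9 · trace/N_c` guards rank deficiency during
  the solve only. Filters are sign-fixed (largest coefficient positive)
  and equal eigenvalues are ordered by the peak-coefficient channel
  index, so outputs are deterministic. Spatial *patterns* (composite
  covariance × filter, normalized) are stored for topography inspection.
* **FBCSP** (7–15, 15–25, 25–30 Hz; 18 features): CSP fitted
  independently per band of the filter bank, features concatenated.
* **BP** (7–30 Hz, one feature per channel, 20 by default): log-variance
  of every channel.

Degenerate flat signals floor the variance at 1e-12 µV² (with a warning)
before the log, so a pathological epoch cannot crash a run.

## Classification

Binary classifiers: LDA; L2-regularized maximum-likelihood logistic
regression (ridge strength chosen by inner 5-fold CV over a log grid,
ties to the stronger penalty); and an RBF-kernel SVM with `(c, γ)` from a
grid search over `c = 2^{-5..15}`, `γ = 2^{-15..3}` in steps of 2 (110
candidates), selected by inner 5-fold CV on training data only, ties to
the smallest `c` then smallest `γ`. The ridge logistic model is a
deliberate, documented stand-in for fast Bayesian logistic regression:
it preserves the linear decision boundary and the regularized fit while
keeping the implementation transparent. Features are standardized with
training-fold statistics.

Multiclass decisions use one-vs-one voting: `K(K−1)/2` binary classifiers
(3 for the 3-class tasks), each with its *own* pair-specific CSP/FBCSP
bank. The class with most votes wins; vote ties fall back to summed
signed confidences, then to the lowest class index in the canonical
order REST < MI-GRASP < MI-ELBOW < MI-ELBOW-GOAL.

Evaluation is 10-fold stratified cross-validation repeated 10 times (100
fold accuracies). The extractor *and* classifier are fitted inside each
training fold — the only leakage-free placement of CSP fitting, possibly
stricter than toolbox defaults that fit spatial filters once on all data.
Stratification (not plain randomization) is imposed so small classes
cannot vanish from a training fold. `best_of_nine()` runs the 3 × 3
extractor/classifier grid under one shared fold plan and reports the
argmax combination as "mean±sd" percent, ties to the first combination
in extractor-major order.

`run_study()` chains everything for a configurable number of virtual
participants (default 12), each with an independent seed and a ±20%
jitter of the modulation parameters to produce between-participant
spread; `compare_tasks()` adds paired t-tests between task tables (a
reporting convenience only). By default the study pools all sessions
into one cross-validation; session-respecting splits are out of scope.

## ERD/ERS and R² maps

`erd_time_course()` implements the percent-change-from-baseline
convention: band-filter (4th-order zero-phase), square, smooth with a
100 ms moving average, average over a class's trials, and reference to
the mean power in a pre-cue window (default −2 to −0.5 s — inside the
guaranteed rest, clear of anticipation). `r_squared_map()` computes, per
channel and per 4-Hz bin spanning 8–24 Hz, the squared Pearson
correlation between single-trial log band power and the binary class
label; `topoplot()` renders such maps by inverse-distance interpolation
over the unit-disc montage.

A numerical caution that shapes several tests: a band-limited power
estimate over bandwidth `B` and window `T` averaged over `M` trials has
relative standard deviation roughly `1/sqrt(2·B·T·M)`, and the baseline
estimate shifts an entire ERD curve coherently. For a 3–4 Hz band and
feasible trial counts this noise floor is several percentage points, so
tests validate *windowed means* at trial counts sized for the tolerance
being asserted (up to 320 trials per class for the ±10-point depth
recovery), never single curve points.

## Problem sizes and determinism

The full paradigm (4 sessions × 20 trials × 4 classes at 1000 Hz) is
supported and is the default configuration; the test suite and examples
run scaled-down versions (fewer trials, 250 Hz, reduced SVM grids, 3–5
fold CV) chosen so each statistical assertion still has the power it
needs. Identical seeds give bit-identical recordings, fold plans, and
reports; all tie-breaks are deterministic.

## Known limitations

* The canonical 20-channel montage is a documented stand-in; any montage
  can be supplied, and topographies are validated against it.
* The generator's linear instantaneous mixing ignores volume-conduction
  blurring; CSP recovery is therefore easier than on real data at equal
  SNR.
* ERD latencies and depths are fixed parameters, not distributions fit
  to data; the ±20% participant jitter is modeling, not inference.
* R² maps are computed on 2 s epochs filtered per bin; for 4-Hz bins at
  250 Hz the effective number of independent power samples per epoch is
  modest, and maps at small trial counts are correspondingly noisy.
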