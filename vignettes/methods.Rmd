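---
title: "Methods: signal model, features and classifier protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal model, features and classifier protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`accelhar` classifies walking, running and jumping from a single triaxial
accelerometer so that activity-specific mechanical loading prediction
equations can be applied to free-living data. This vignette documents the
scientific choices behind each stage: the signal and feature model, the
tunable parameters and their defaults, the synthetic data generator, the
numerical conventions, and the limitations of what the test suite can
demonstrate.

## Signal model and windowing

A recording is a continuous x/y/z acceleration stream in gravitational
units (1 g = 9.807 m s⁻²) at a nominal 100 Hz with a ±16 g dynamic range;
y is the vertical axis under the usual wear orientation. Activity bouts are
stored as 0-based half-open sample intervals `[start, end)` and cut into
windows of `round(fs × window_seconds)` samples. Defaults: 1 s windows with
a stride equal to the window (non-overlapping). Overlap is exposed as a
parameter because window counts in validation studies of this design are
not generally recoverable; a trailing partial window is dropped, and
windows never span bout boundaries, so each window has exactly one label.
The emitted count per segment is `max(0, floor((len − W)/S) + 1)`.

Out-of-range samples (>16 g in magnitude) indicate clipping or export
faults; the reader rejects them by default and can clip with a warning
instead.

## The 54-feature vector

Per 1 s window the extractor computes, in a fixed documented column order:

* per axis: mean, SD (sample, n−1), coefficient of variation, skewness,
  excess kurtosis, min, 25th percentile, median, 75th percentile, max
  (30 features);
* mean and SD of the resultant magnitude r = √(x² + y² + z²) (2);
* FFT features for each of x, y, z and r: dominant frequency, dominant
  magnitude, total power, median frequency (16);
* pairwise Pearson correlations corr_xy, corr_xz, corr_yz (3);
* orientation angles roll, pitch, yaw (3).

The per-axis time-domain list plus magnitude, correlation and orientation
features total 50 when spectral features cover only the three axes. The
extractor therefore also computes the four spectral features on the
resultant magnitude, the most parsimonious composition that reaches the
documented 54; the composition is a single constant (`feature_names()`), so
an alternative reading is a one-line change.

Numerical conventions, pinned so results are reproducible across
implementations:

* `cv = sd / max(|mean|, 1e-6)` — the guard keeps the ratio bounded on
  zero-mean horizontal axes, which matters because downstream
  standardization cannot absorb infinities.
* Skewness `m₃/m₂^1.5` and excess kurtosis `m₄/m₂² − 3` use central moments
  with n denominators; a constant series has skew = kurt = 0 by convention.
* Percentiles interpolate linearly between order statistics
  (`stats::quantile` type 7).
* Spectra are computed on the mean-removed series and the DC bin is
  excluded from all four spectral features — otherwise the gravity offset
  dominates every window's "dominant frequency". Total power excludes DC
  for the same reason. Dominant-frequency ties resolve to the lowest
  frequency; a constant series reports zero magnitude/power at the lowest
  bin.
* Correlations of a zero-variance axis pair are 0 by convention.

### Orientation angles

Each axis is low-pass filtered (2nd-order Butterworth, 1 Hz cutoff) forward
and backward so the net phase response is zero, isolating the quasi-static
gravity component; the filtered window means (gx, gy, gz) give
`roll = atan2(gy, gz)`, `pitch = atan2(−gx, √(gy² + gz²))`,
`yaw = atan2(gx, gy)`. Yaw — rotation about gravity — is not observable
from a static accelerometer; the formula is a fixed convention kept for
schema completeness, and no claim is made that it matches any particular
heading definition.

Zero-phase filtering on 1 s windows is numerically delicate: at a 1 Hz
cutoff and 100 Hz sampling the recursion settles over tens of samples, so a
naive zero-state forward–backward pass corrupts most of the window. The
implementation pads each end with 9 samples of odd reflection and seeds the
recursion with the filter's steady-state initial conditions scaled to the
padded edge value. A constant series then passes through exactly, and a
zero-mean tone at ten times the cutoff perturbs the window mean by under
1% of its amplitude, which is what the angle estimates consume.

## Synthetic data generator

The simulator emulates a laboratory protocol: each participant performs 9
walking, 6 running and 22 jumping trials while wearing one sensor. Per
trial the vertical axis carries +1 g plus an impact train; horizontals
carry correlated oscillation at the cycle frequency; white noise
(SD 0.05 g) is added to all axes. Defaults, chosen once as representative
of adult locomotion and fixed:

| parameter | walking | running | jumping |
|---|---|---|---|
| cycle frequency (Hz) | 1.5–2.2 | 2.4–3.2 | 0.8–1.6 |
| peak amplitude above gravity (g) | 0.3–0.8 | 1.5–3.5 | 3.0–7.0 |
| trial duration (s) | 3 | 2 | 2 |

Trial durations reflect mid-corridor walking/running passes and single jump
tasks of a few seconds each. Impacts are half-sine pulses with a 20% duty
cycle — band-limited, with an analytically predictable dominant frequency
at the cadence, which is what the spectral-feature tests rely on. Running
adds a brief low-g aerial phase; jump cycles contain a near-0 g flight
interval (20–40% of the cycle) followed by a landing spike, mirroring the
free-fall/landing structure that makes running and jumping the confusable
pair in practice. Placement scales amplitudes (ankle 1.4, hip 1.0, lower
back 0.9: distal sensors see larger impact accelerations). Per-participant
multiplicative lognormal effects (σ = 0.1) perturb cadence and amplitude.
One global seed determines everything; participant streams use documented
sub-seeds (`seed + 77003·i`) so a single participant can be regenerated
alone.

What the simulator does *not* model: biomechanically faithful ground
reaction forces, soft-tissue artifact, orientation drift, transitions,
non-target activities, or the heavy overlap between fast running and low
jumping seen in real cohorts. Its classes are far more separable than real
data — the default cohort is classified near-perfectly by all three
algorithms. Passing the pipeline's tests therefore demonstrates
*correctness of the machinery* (no leakage, reproducibility, metrics
computed as defined), not field accuracy; the published reference confusion
matrices shipped with the package are the anchor for metric-level
correctness on realistic error structures.

## Split, preprocessing and tuning protocol

The train/test split is at the participant level (80/20, nearest integer),
stratified by each participant's activity-window composition (quartiles of
jumping fraction) so class proportions match across sides; with a fixed
protocol all compositions are near-identical and the stratification
degenerates gracefully to a random participant split. At least five
participants are required.

Features pass a near-zero-variance filter — drop on zero variance, or on
(most-common/second-most-common frequency ratio > 19 AND unique values
< 10% of rows), the conventional 95/5 + 10% thresholds, both exposed as
knobs — then are standardized with training-set means and SDs. Inside
cross-validation the filter and scaler are re-fitted on each fold's
analysis portion, so no assessment information reaches preprocessing.

Cross-validation folds partition the training *participants* (5 folds by
default). Grouping by participant is the conservative choice given the
participant-level outer split: window-level folds would let a person's
gait appear on both sides of a fold and inflate tuning estimates.

Hyperparameter grids are seeded Latin-hypercube draws of 10 settings over:
`mtry` ∈ [1, p], `min_n` ∈ [2, 40] (RF, 500 trees fixed); `cost` ∈
2^[−5, 10], `rbf_sigma` ∈ 10^[−4, 0] (SVM-RBF); `n_neighbors` ∈
[1, 2·round(√n)] (KNN). The ranges are this package's choices; they cover
the usual operating regions including deliberately weak corners.

### Model selection

The winning setting maximizes mean CV **percent agreement**, with ties
broken by mean macro ROC-AUC, then mean Kappa, then lower model complexity
(fewer sampled predictors / lower cost / more neighbors). Agreement leads
for a concrete reason observed during development: with well-separated
classes, rank-based ROC-AUC saturates near 1 across most of the grid and
can rank an underfit SVM — whose decision values still order the classes
correctly but whose hard labels are poorly calibrated — above a
well-calibrated one. Selecting on agreement penalizes exactly that failure
while the AUC tie-break preserves ranking quality.

### SVM probabilities

Class probabilities for the SVM are derived from the one-vs-one decision
values: each pairwise decision passes through a logistic link and the
per-class votes are normalized to sum to one. This is an approximation —
it is monotone in the decision values (so AUCs are meaningful) but not a
calibrated posterior; it avoids fitting a separate probability model
inside every CV fold. RF probabilities are the probability forest's
ensemble vote fractions; KNN probabilities are neighbor vote fractions.

## Evaluation

Percent agreement is 100·trace/N of the predicted-by-observed confusion
matrix (fixed class order walking, running, jumping; column percentages
are per observed class). Cohen's κ = (p₀ − pₑ)/(1 − pₑ) with pₑ from the
marginals; degenerate marginals (pₑ = 1) return 0 with a warning. One-vs-all
ROC-AUC uses the midrank formulation (ties count one half), per class, with
an unweighted macro mean; classes absent from the observed labels are
excluded with a warning. The macro mean is a convention choice — per-class
AUCs are convention-free and reported alongside. Per-activity agreement
and kappa come from collapsing the 3×3 table to the one-vs-rest 2×2 table.

Permutation importance shuffles one feature column at a time in the
held-out matrix (10 repeats by default, seeded) and reports the drop in
agreement against the unshuffled baseline, sorted descending. Held-out
rows are used rather than training or out-of-bag rows so the importance
reflects generalization. On the default synthetic cohort most importances
are near zero despite perfect accuracy: the 54 features are highly
redundant there, and destroying one leaves many perfect substitutes —
another reminder that simulator results characterize the machinery, not
real-data feature rankings.

## Determinism and problem sizes

Every stochastic stage takes an explicit seed (simulation, split, grid,
folds, model fits, permutation); `run_pipeline()` refuses configs with a
missing seed and writes byte-identical reports on re-runs. KNN prediction
tie-breaking is seeded explicitly because the underlying implementation
breaks exact-distance ties randomly.

The shipped test suite and acceptance script run the full default study —
48 participants, ~4,000 windows, 10-setting grids, 5-fold grouped CV for
all three algorithms — in a few minutes on one CPU; unit tests use smaller
seeded cohorts (6–12 participants) chosen to keep each property check
fast while still exercising grouped splits and folds.

## Known limitations

* Yaw is reported but not identifiable from gravity alone.
* SVM probabilities are uncalibrated approximations (ranking-faithful).
* The simulator's separability overstates real-world accuracy by design.
* Free-living data — unsegmented streams, transitions, non-target
  movements — are out of scope; the pipeline assumes labeled bouts.
* Proprietary binary exports (e.g. .gt3x) are not parsed; input is CSV.
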