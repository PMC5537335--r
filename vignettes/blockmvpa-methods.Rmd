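---
title: "Block-design MVPA with permutation-based inference: models and design choices"
author: "blockmvpa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Block-design MVPA with permutation-based inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`blockmvpa` implements a complete decoding analysis for block-design
fMRI region-of-interest (ROI) data: per-block response estimation via a
double-gamma haemodynamic response function (HRF) general linear model,
pairwise condition decoding with a linear support vector machine (SVM)
under leave-one-run-out cross-validation, a run-wise label-permutation
estimate of the empirical chance level, and nonparametric group
inference. A synthetic-data module supplies multi-subject two-session
cohorts with known ground truth, so the statistical behaviour of every
stage is testable.

This vignette documents the models, the tunable parameters, the design
choices made where a published description leaves the procedure
underdetermined, and the limits of what the synthetic validation shows.

# The signal and noise model of the simulator

Each simulated run is a voxels x volumes matrix

$$ Y = A \cdot X^\top + E + D + S $$

* $X$ (volumes x blocks) holds one HRF-convolved unit boxcar per
  stimulus block, sampled at volume times $k \cdot TR$ (convolution at
  0.1 s resolution).
* $A$ (voxels x blocks) assigns each block its voxel amplitude vector:
  the mean pattern of the block's condition. Condition mean patterns are
  a shared baseline (mean 1, SD 0.2 across voxels) plus offsets along
  random orthonormal directions, constructed by classical
  multidimensional scaling so that every condition pair's Euclidean
  distance equals exactly $d \,\sigma \sqrt{V}$ — i.e. a per-voxel
  root-mean-square mean difference of $d$ noise-SD units. Inconsistent
  pairwise distances (violating Euclidean realizability) are rejected.
* $E$ is stationary AR(1) Gaussian noise per voxel (marginal SD
  `noise_sd`, default 1; coefficient `ar1_coef`, default 0.3 — a typical
  BOLD autocorrelation at TR = 2 s).
* $D$ is per-voxel slow drift: linear + quadratic terms with random
  coefficients of SD `drift_amplitude` (default 0.5).
* $S$ adds motion spikes: each volume is flagged with probability
  `spike_rate` (default 0.01) and offset by
  `spike_magnitude` x `noise_sd` (default 8) in a random 3–8% voxel
  subset, so the spike-detection rule (strictly more than 2% extreme
  voxels) can fire.

The experimental geometry defaults to the study conditions the package
models: 2 sessions (deprived, satiated), 3 runs/session, 3 conditions
(cigarette, pencil, chair), 8 blocks per condition per run, blocks of
8 stimuli x (1500 + 50) ms = 12.4 s (the trailing inter-stimulus
interval is counted into the block), rests drawn uniformly from
{10, 12, 14} s, TR = 2 s, 10 subjects. The localizer simulator uses its
own timing: 12 + 12 blocks of 12 stimuli x (1200 + 600) ms = 21.6 s,
12.6 s fixation intervals, TR = 1.8 s.

Between-subject variability is a ±20% jitter of the noise SD and
independently drawn pattern directions per subject; the standardized
separations $d$ are preserved exactly for every subject.

## Default effect sizes

The default `pattern_separation` values (cigarette|pencil: d = 0.02
deprived, 0.005 satiated; chair pairs: d = 0.035) were fixed once, at
design time, so that default-configuration decoding accuracies at
V = 200 fall in the 53–80% range characteristic of published
block-design object decoding, with the cigarette–pencil contrast
decodable only in the deprived session. The per-voxel values are small
because the simulator's noise is voxelwise independent: pooling V
independent voxels multiplies pattern discriminability by roughly
$\sqrt{V}$, whereas real BOLD noise is spatially correlated and far less
compressible. This is the main respect in which passing synthetic tests
understates the difficulty of real data (see *Limitations*).

# Preprocessing

**High-pass filter.** "Removing frequencies below 6 cycles per run" is
implemented as projection: each voxel's time course is residualized
against an intercept, a linear trend, and sine + cosine pairs at 1–5
cycles per run. Both quadratures are included because a drifting
physiological rhythm has arbitrary phase; a cosine-only basis could not
remove it. Projection makes the filter idempotent and leaves frequencies
at or above 6 cycles/run attenuated by < 5%.

**Spike detection.** Per volume, the fraction of voxels whose intensity
deviates from their own temporal mean by more than 4 temporal SDs
(two-sided — signal drops are as pathological as spikes). The mean and
SD are computed once over all volumes; voxels with zero variance are
excluded from the denominator. The comparison is strict on both
thresholds (4 SD, 2%), so a volume with exactly 2% extreme voxels is
not flagged.

**Scrubbing.** Interior flagged volumes are replaced per voxel by a
natural cubic spline through all unflagged volumes. Flagged volumes at a
run edge have no clean bordering volume on one side, so they — and any
flagged volumes contiguous with the edge — are deleted; a kept-volume
map lets block onsets be re-expressed (`preprocess_run()` shifts onsets
by the number of deleted leading volumes x TR).

# Beta-series GLM

The HRF is the difference of two gamma-density lobes, each parameterized
by its mode (shape = 1 + delay/dispersion), peak-normalized, with the
undershoot subtracted at relative weight 1/6 and the result rescaled to
peak 1. Defaults: peak at 6 s, undershoot at 16 s, dispersions 1 s,
32 s support — the canonical double-gamma values, exposed in
`hrf_params()` because the source analyses rarely state them.

Block amplitudes are estimated by **one joint OLS fit per run** with one
regressor per block plus an intercept ("least-squares-all"). With ≥10 s
rests the block regressors are nearly orthogonal (pairwise |r| < 0.3),
so the joint fit is well-posed and equivalent in expectation to separate
fits while handling residual overlap correctly. Rank deficiency is
reported with the offending columns.

**Z-scoring.** Each block's pattern is standardized across voxels to
mean 0, SD 1. Two conventions were open: per block across voxels
(adopted — it matches the notion of normalizing "across all voxels
within the ROI") versus per voxel across blocks. The SD uses the n−1
(sample) denominator, the convention under which the three-voxel pattern
(1, 2, 3) maps to (−1, 0, 1); this is documented and fixed. Because each
block is normalized using only its own voxels, z-scoring cannot leak
information between cross-validation folds.

# Decoding and the empirical chance level

`train_linear_classifier()` solves the standard soft-margin C-SVC dual
(hinge loss, penalty C = 1) by sequential minimal optimization (SMO)
with maximal-violating-pair selection, implemented in C++ against a
precomputed Gram matrix. The kernel-level interface matters: a
permutation test retrains the classifier thousands of times on the same
examples with different labels, and reusing one Gram matrix makes each
refit microseconds instead of milliseconds. The solver is cross-checked
in the test suite against libsvm (`e1071::svm`) and an interior-point QP
solution of the dual (`kernlab::ipop`). Decision values of exactly zero
go to the alphabetically first class label — an arbitrary but
deterministic tie rule.

Leave-one-run-out cross-validation trains on all runs but one and tests
on the held-out run; with the default design each fold has 16 training
and 8 test examples per condition, and the mean fold accuracy is
reported in percent.

The **empirical chance level** replaces the nominal 50% baseline:
condition labels are shuffled independently within each run (preserving
each run's label counts, hence the run-exchangeability structure), the
classifier is retrained for every fold, and the cross-validated accuracy
is recorded; 1000 seeded iterations form the null distribution. By
default only training-fold labels are shuffled and accuracy is scored
against the true test labels; a `train_and_test` scope (shuffle
everywhere, score against the permuted labels) is provided, as both
destroy the label–pattern association and yield valid nulls. On small
enumerable problems the sampled null mean matches exhaustive enumeration
of all within-run shuffles.

# Group inference

* **Accuracy vs chance.** Paired Wilcoxon signed-rank test of
  per-subject accuracy against the per-subject permutation-null mean.
  Zero differences are dropped, ties get midranks, W is the smaller
  signed-rank sum, and for n ≤ 15 the two-sided p is exact by
  enumeration of all 2^n sign assignments (valid under ties); larger n
  uses the tie-corrected normal approximation with continuity
  correction. Sidedness was unstated in the source description;
  two-sided is the conservative choice.
* **Session difference.** The same paired test applied to per-subject
  deprived-minus-satiated accuracy differences versus the matching
  differences of null means.
* **FDR.** Benjamini–Hochberg step-up adjustment (via
  `stats::p.adjust`), applied within each ROI variant's family of nine
  p-values (six accuracy-vs-chance, three session-difference tests);
  both uncorrected and adjusted p-values are always reported.
* **Interaction.** The repeated-measures interaction F for the
  2 (session) x 3 (pair) within-subject design, computed from the
  closed-form sum-of-squares decomposition with the
  interaction x subject term as error (cross-checked against
  `stats::aov`). Its permutation null shuffles the six cell values
  independently within each participant — the exchangeability implied by
  "no condition effects" — for 10,000 seeded iterations; a
  between-participant whole-vector scope is available behind a flag. The
  p-value uses the (1 + b)/(1 + m) estimator, which cannot return zero.
  Planned pairwise comparisons are run regardless of the interaction
  outcome.

# Numerical and degenerate-input choices

* Noiseless localizer fits have zero residual variance; t statistics are
  capped at a documented sentinel of ±1e6 rather than returning NaN.
* The interaction F uses a mean-square floor of 1e−12, so exactly
  additive tables return F ≈ 0 instead of 0/0.
* All stage seeds are derived deterministically from one global seed
  (kept inside the 32-bit signed range); identical configurations give
  bit-identical results end to end.
* `scrub_volumes` refuses to run when fewer than two unflagged volumes
  remain; `highpass_filter` names the minimum volume count it needs.

# Problem sizes used in validation

The shipped tests validate calibration at deliberately desk-scale sizes,
chosen as the package's own trade-off between statistical resolution and
suite runtime: empirical-chance checks on 2 simulated subjects at
V = 60 with 1000 permutations; effect-size recovery at V = 60 over
100 (d = 0) and 30 (other d) replicates; group-test type-I error over
500 null cohorts of 10 subjects at V = 30 with 30 permutations each;
interaction-p uniformity over 500 null tables at 400 permutations
(500 rather than 200 replicates because the expected Kolmogorov–Smirnov
deviation of a perfectly uniform sample at n = 200, about 0.06, exceeds
the 0.05 acceptance band the check uses). The acceptance script runs the
full study geometry: 10 subjects, V = 200, 1000 permutations per
subject.

# Limitations

* The simulator's noise is voxelwise independent; real BOLD noise is
  spatially correlated, so real-data accuracies for a given per-voxel
  effect size will be lower than synthetic ones. Passing recovery tests
  demonstrates the correctness of the machinery, not field-strength
  effect sizes.
* No spatial preprocessing is modelled or performed (motion, distortion,
  normalization, smoothing); volumes enter as ROI matrices.
* The localizer stage operates on a candidate voxel set, not whole-brain
  images; anatomical constraints on ROI definition are out of scope.
* The beta GLM includes no nuisance regressors beyond the intercept
  (high-pass filtering precedes it); motion-parameter regression is not
  modelled.
* T1-saturation start-of-run volumes are not simulated; generators emit
  steady-state series.
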