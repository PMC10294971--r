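---
title: "Segment-level CVD detection from PPG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segment-level CVD detection from PPG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgcvd)
```

ppgcvd implements a complete segment-level pipeline for detecting
cardiovascular disease (CVD) from single-channel photoplethysmogram (PPG)
recordings: a seeded synthetic cohort generator, one-second segmentation,
five dimensionality-reduction (DR) methods mapping each 200-sample segment
to 100 features, a descriptor panel, twelve classifiers under one
coded-target contract, and a stratified 10-fold evaluation grid. This
vignette explains the models, the tunable parameters, and the design
decisions taken where the procedure was genuinely open.

## The study shape

The pipeline assumes a cohort of 41 subjects (20 CVD, 21 normal), each
contributing 144,000 samples at 200 samples/s. One second of signal is the
classification unit, so each subject yields a 720 x 200 segment matrix and
the cohort 29,520 segments (14,400 CVD + 15,120 normal). Two nominally
reported acquisition figures conflict with these counts (a 300 Hz sampling
rate, and an 8-minute duration); the package adopts 200 samples/s and
720 s per subject because every printed segment count follows from exactly
that arithmetic, and it is the segment bookkeeping, not wall-clock
duration, that the downstream stages consume.

## The synthetic cohort generator

Real reference recordings are not redistributable, so `generate_cohort()`
draws cohorts with the structural properties the pipeline assumes. Each
beat is a sum of two Gaussian lobes — a unit-amplitude systolic peak
(center 0.25 of the beat, width 0.05) and a dicrotic wave (amplitude 0.5,
center 0.58, width 0.16) — concatenated over beat intervals drawn from a
Gamma distribution (mean 60/72 s, coefficient of variation 0.04). White
noise (default sd 0.05, i.e. 5% of the systolic amplitude, a typical
pulse-oximeter noise floor) and sparse motion-artifact bumps (default 0.2
events/min, amplitude 1–2.5, width 0.2–0.6 s) are added on top.

`morphology_shift` in [0, 1] is the class-separability dial: for CVD
subjects the dicrotic amplitude is multiplied by `1 - 0.6 * shift`, the
systolic width by `1 + 0.4 * shift`, and the interval coefficient of
variation by `1 + 0.5 * shift`. At `shift = 0` the classes are
distributionally identical; separability of raw segments under a
nearest-centroid probe rises monotonically with the dial (roughly 0.5,
0.68, 0.84 at 0.1, 0.5, 0.9 on a small cohort). The base template
constants were chosen so that the two CVD effects do not cancel in the
segment mean; with a narrower dicrotic wave they nearly do, which makes
the cohort unlearnable by linear probes at any shift.

What the generator does *not* emulate: baseline wander, respiratory
modulation, sensor saturation, and the rich subject-to-subject morphology
differences of real cohorts. Crucially, one-second segments inherit a
random beat phase. Distance- and margin-based classifiers (SDC, kNN,
logistic, LDA) tolerate this and exceed 90% segment accuracy on separable
cohorts, but unsupervised and fluctuation-based kinds (EM, PCA-threshold,
DFA) sit near chance on phase-confounded envelope features. Passing tests
on this cohort therefore demonstrate pipeline correctness and the relative
robustness of classifier families — not clinical performance.

## Dimensionality reduction: 200 samples to 100 features

**Hilbert envelope** (`ht_reduce`). The analytic signal `x + iH(x)` is
formed in the frequency domain (negative half-spectrum zeroed, positive
doubled); its magnitude is the instantaneous envelope. The reduction keeps
the envelope at the 100 even (0-based) sample positions. Decimation by two
was chosen because the envelope of a sub-Nyquist pulse waveform is smooth
at that scale; the envelope is also bounded below by |x| pointwise, which
the tests assert.

**Nonlinear regression** (`nlr_reduce`). Each segment is fitted with a sum
of `n_kernels = 4` Gaussian lobes by Levenberg–Marquardt least squares
(three starts, best residual sum of squares kept), and the fitted curve is
evaluated at 100 equispaced points. Four kernels give the two-lobe pulse
morphology headroom for asymmetric or artifact-bearing segments. Kernel
widths are bounded in (0.005, 5) segment lengths; the generous upper bound
lets the family approximate constant segments, so the fit is never worse
than the best constant.

**Swarm column selection** (`abc_pso_select`, `cuckoo_select`,
`dragonfly_select`). The heuristic methods are interpreted as selecting
100 of the 200 per-segment sample positions, shared across the cohort.
All three optimize the wrapper fitness
`F = a * phi(K) + b * (T - K) / T` with `a = 0.8`, `b = 0.2`, where
`phi` is the hold-out accuracy of a nearest-centroid evaluator on the
selected columns (deterministic stratified 70/30 split) — the only reading
of the printed fitness under which `F` is a bounded score. Candidates live
in a continuous position space, are squashed through a sigmoid,
thresholded at 0.5, and *repaired* to exactly 100 columns by flipping the
lowest-impact bits under a per-column class-separation ranking.

Design choices that matter:

* **Initialization.** Each individual receives an additive position bias
  spread over [-2.5, 2.5], so initial selection counts range from
  near-empty to near-full. Repair then concentrates high-count candidates
  on the strongest columns, giving the population a well-spread,
  informative start; without it every candidate starts near 100 arbitrary
  columns and the wrapper fitness is almost flat in the overlap with the
  informative set.
* **Fitness subsampling.** Fitness is evaluated on a deterministic
  stratified subsample of at most 512 segments, keeping full-cohort
  selection (29,520 x 200) at a few seconds per run without changing the
  selected masks' character.
* **Levy flights** use Mantegna's sampler with exponent `levy_gamma`
  (default 2.5, density tail `|step|^-gamma`, stability index
  `gamma - 1`); a Hill-estimator test checks the tail.
* **Dragonfly enemy term.** The additive enemy offset (`Q- + Q`) is
  implemented as printed in the source description, with
  `enemy_conventional = TRUE` switching to the conventional difference.
* Elitism in all three: the best-so-far fitness trace is non-decreasing.

## The descriptor panel

`stats_summary()` reports, per class: mean, sample variance, Fisher
skewness, *excess* kurtosis (the convention consistent with reported
values near -1 for flat and +5 for peaked data), the mean within-class
Pearson correlation over segment pairs (subsampled to at most 10,000
pairs, seeded), the average per-subject sample entropy (`m = 2`,
`r = 0.2` sd, computed on a length-capped subsequence of the pooled
features — the standard SampEn defaults, since no parameters are
recoverable from the source tables), and the first canonical correlation
between the class feature sets (ridge-regularized whitening). CCA needs
paired observations; segments are paired by temporal index, which makes it
the one descriptor that is not invariant to segment reordering.

## Twelve classifiers, one contract

Every classifier fits on a feature matrix with labels coded to real
targets (`t_cvd = 0.85`, `t_normal = 0.1`, gap constraint >= 0.5), emits a
score in [0, 1] per segment, and thresholds it; `label = score >=
threshold` exactly, which the tests assert. Iterative kinds stop at a
criterion of 1e-5 or 1000 iterations, whichever comes first.

| kind | model | threshold |
|---|---|---|
| PCA | first-principal-axis projection, min-max normalized, CVD high | 0.72 (stated) |
| EM | 2-component diagonal-Gaussian EM on pooled features; components mapped to classes by training majority | 0.5 |
| LOGREG | full-batch gradient descent on standardized features | 0.5 (stated) |
| GMM | one 2-component mixture per class; dimension-normalized log-likelihood ratio | 0.5 |
| BLDC | pooled-covariance Gaussian discriminant, equal priors, D = 0 | 0.5 |
| FIREFLY | population of class-prototype pairs; brightness 1/MSE | 0.475 (midpoint) |
| HARMONY | harmony memory of prototype pairs, bandwidth 0.004 | 0.475 (midpoint) |
| DFA | per-segment scaling exponent; nearest class-mean exponent | 0.5 |
| PAC_BAYES | Gibbs vote over single-feature threshold stumps (decile cuts, both orientations), posterior `exp(-4 n err)` | 0.5 |
| KNN_PAC | kNN in the feature space augmented with the PAC-Bayes score; k from {3, 5, 7} by validation | 0.5 |
| SDC | `log sum exp(-0.5 ||x - x_i||^2)` per class | 0.5 |
| DETREND_SDC | per-window linear detrending of each feature vector, then SDC | 0.5 |

Numerical and design notes:

* **EM / GMM** use diagonal covariances with a variance floor; the
  log-likelihood trace is asserted non-decreasing inside every fit.
  Reported optimal-parameter strings for EM ("likelihood probability
  0.15, cluster probability 0.6, convergence rate 0.6") do not map onto
  standard EM quantities and are surfaced only as configuration comments.
* **BLDC** shrinks the pooled covariance 5% toward a scaled identity:
  envelope feature panels are strongly correlated and the raw pooled
  estimate is ill-conditioned when n is comparable to p (without
  shrinkage, LDA accuracy collapses on such panels).
* **FIREFLY / HARMONY** are described in their source only as optimizers;
  the minimal classifier construction consistent with "class harmony
  fixed at the target values" is adopted: optimize a pair of class
  prototypes against the coded-target MSE of nearest-prototype
  predictions, classify by proximity. Populations are warm-started at the
  empirical class means plus jitter (harmony memory also holds uniform
  random members); attractiveness uses absorption beta = 1 (no value is
  stated) with squared distance averaged over dimensions so attraction
  does not vanish in 200-dimensional prototype space. Stagnation windows
  (25 / 200 improvisations) bound runtime; best-MSE traces are
  non-increasing by elitism.
* **DFA** uses windows {4, 8, 16, 32} on 100-feature rows (the stated
  window constants K = 10000, M = 1000, n = 100 cannot apply to
  100-sample inputs) and a geometric grid within [3, len/2] for shorter
  rows. A constant series (linear profile) makes every fluctuation vanish
  and is flagged.
* **SDC / KNN_PAC** subsample their reference sets (500 and 1000 per
  class) on large cohorts, seeded, to bound the quadratic distance cost.

## Evaluation protocol

`run_grid()` reduces the pooled cohort once per method, then runs
stratified 10-fold cross-validation at segment level (per fold: fit on
90%, score 10%), mirroring how per-segment performance tables are
reported; subject-level folds — the honest generalization test, since
segments of one subject are heavily dependent — are available via
`subject_level = TRUE`. Reduction happens before fold splitting (the
selectors see all labels), which reproduces the upstream protocol and its
leakage; per-fold re-selection would multiply cost tenfold and is out of
scope. Confusion counts take CVD as positive. The metric suite is

* PI = (TP + TN - FN - FP) / (TP + TN) x 100
* sensitivity = TP / (TP + FN) x 100, specificity = TN / (TN + FP) x 100
* accuracy = (TP + TN) / total x 100
* GDR = (TP + TN - FP) / (TP + TN + FN) x 100
* error rate, reported as 100 - accuracy so the pair sums to 100 exactly
  in floating point (it equals (FP + FN) / total x 100 to the last ulp).

Undefined ratios (zero denominators) are flagged as NA rather than
silently dropped. Fold averages are unweighted means.

## Test fixtures and problem sizes

The test suite builds every fixture in code. Two deserve explanation:

* **Gaussian blob pairs** (`generate_feature_blobs`): identity-covariance
  classes with means `separation` apart. The mean-difference direction is
  a square wave along the feature index with three amplified coordinates,
  chosen so that every classifier family can see the difference —
  location (distance and linear kinds), single-coordinate offsets
  (threshold stumps), and low-frequency serial structure that per-window
  detrending does not annihilate (fluctuation kinds). Learning-sanity
  checks run at 100 features, the pipeline's native dimension;
  fluctuation exponents estimated from 10-sample rows are too noisy to
  separate anything, whatever the direction.
* **Planted-column recovery**: 100 informative columns (0.5 sd per-column
  class separation) among 200, 150 rows per class; each selector must
  recover at least 80% of the informative set as the median over 10
  seeds at population 20 and 30 generations.

Deterministic test problem sizes keep the default suite at roughly a
minute: cohorts of 2–8 subjects at 5–60 s for unit tests, with the full
41-subject, 144,000-sample cohort exercised once in the acceptance suite
for the structural counts and reduction dimensions.

## Known limitations

* The synthetic cohort is a structural stand-in; absolute accuracies on
  it say nothing about clinical data, and the headline accuracies of the
  motivating study are not reproducible without the withheld recordings.
* Single-channel "ICA" denoising is ill-posed; the implemented
  segments-as-variables whitening with max-kurtosis component removal is
  a pragmatic artifact filter, off by default.
* Segment-level folds leak subject identity across train/test; use
  subject-level folds for honest generalization estimates.
* The PCA classifier's fixed 0.72 threshold is asymmetric by design and
  costs sensitivity on symmetric two-cluster score distributions.
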