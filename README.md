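# ppgcvd

Segment-level detection of cardiovascular disease (CVD) from
single-channel photoplethysmogram (PPG) recordings, for researchers
working on physiological time-series classification who need a tested,
reproducible reference pipeline rather than a clinical device.

A PPG trace is a quasi-periodic pulse waveform (systolic peak plus
dicrotic wave). The pipeline treats each one-second segment (200 samples)
as the classification unit: a 41-subject cohort (20 CVD, 21 normal) with
144,000 samples per subject yields 720 segments per subject and 29,520
segments in total. Each stage is exposed as ordinary R functions:

1. **Cohort** — `generate_cohort()` draws seeded synthetic two-class
   cohorts from a two-lobe Gaussian beat model with Gamma-distributed
   beat intervals, white noise and motion artifacts (real signals can be
   supplied as CSV + JSON labels via `read_cohort()`).
2. **Segmentation** — `segment_record()` cuts signals into contiguous
   one-second rows; `denoise_segments()` optionally removes the
   highest-kurtosis whitened component.
3. **Dimensionality reduction** (200 → 100 features per segment) by five
   methods: the Hilbert-envelope decimation
   (|x + iH(x)| at even sample positions), a Levenberg–Marquardt fit of
   f(t) = Σ A_g exp(−(t−c_g)²/2w_g²) evaluated at 100 points, and three
   swarm searches (hybrid bee-colony/PSO, cuckoo search with Lévy
   flights, dragonfly) selecting 100 of the 200 sample positions under
   the wrapper fitness F = 0.8·φ(K) + 0.2·(T−K)/T.
4. **Classification** — `ppg_classifier()` fits any of twelve classifiers
   (PCA projection, EM, logistic regression, GMM, Bayesian LDA, firefly,
   harmony search, detrended fluctuation analysis, PAC-Bayes stumps,
   kNN over PAC-Bayes scores, softmax discriminant, detrend + SDC) under
   one contract: train against coded targets (0.85 for CVD, 0.10 for
   normal), emit a score per segment, threshold to a label.
5. **Evaluation** — `run_grid()` crosses methods × classifiers under
   stratified 10-fold (90/10) cross-validation and reports the
   confusion-matrix suite: PI = (TP+TN−FN−FP)/(TP+TN)·100, sensitivity,
   specificity, accuracy, GDR = (TP+TN−FP)/(TP+TN+FN)·100 and error
   rate, with accuracy + error = 100 exactly.

`run_pipeline()` ties the stages together from a `run_config()` or YAML
file and writes fold-level/summary CSVs plus a reproducibility manifest;
`inst/cli/ppgcvd.R` is a thin command-line wrapper over the same
functions.

## Worked example

```r
library(ppgcvd)

cohort   <- generate_cohort(cohort_spec(n_cvd = 3, n_normal = 3,
                                        duration = 60,
                                        morphology_shift = 0.8, seed = 42))
segments <- lapply(cohort, segment_record)
features <- reduce_features(segments, "HT")       # Hilbert envelopes
x <- do.call(rbind, lapply(features, `[[`, "features"))
y <- pool_segments(segments)$y

train <- seq_along(y) %% 2 == 1
model <- ppg_classifier(x[train, ], y[train], "SDC", seed = 1)
model
#> PPG segment classifier: SDC
#>   trained on 180 segments x 100 features
#>   score threshold 0.5; coded targets 0.85 / 0.10
#>   final training MSE 0.02635 (1 criterion evaluations)

pred <- predict(model, x[!train, ])
confusion_counts(y[!train], pred)
#> tp=89 tn=89 fp=1 fn=1
```

The metric suite on those counts gives an accuracy of 98.89%, a good
detection rate (GDR) of 98.88% and a performance index (PI) of 98.88%:
of 180 held-out segments the softmax discriminant classifier mislabels
one CVD and one normal segment. On the same cohort a 5-fold grid
(`run_grid(segments, methods = "HT", kinds = c("BLDC", "SDC",
"HARMONY"), n_folds = 5, seed = 7)`) prints fold-averaged accuracies of
66.1% (BLDC), 61.1% (HARMONY) and 98.3% (SDC) — the phase-randomized
synthetic segments are easy for distance-based classifiers and hard for
linear or prototype ones, a contrast discussed in the methods vignette
(`vignettes/ppgcvd-methods.Rmd`).

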