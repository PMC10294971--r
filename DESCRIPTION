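Package: ppgcvd
Title: Cardiovascular Disease Detection from Photoplethysmogram Segments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segment-level classification of cardiovascular disease from
    single-channel photoplethysmogram (PPG) recordings. Provides a seeded
    synthetic two-class cohort generator with a two-lobe (systolic plus
    dicrotic) beat model, one-second segmentation, five dimensionality
    reduction methods (Hilbert-envelope decimation, Gaussian-kernel nonlinear
    regression, and three swarm-based sample-position selectors: hybrid bee
    colony with particle swarm updates, cuckoo search with Levy flights, and
    the dragonfly algorithm), a statistical descriptor panel (moments,
    Pearson correlation, sample entropy, canonical correlation), twelve
    classifiers under a common coded-target contract, and a stratified
    10-fold evaluation grid reporting performance index, sensitivity,
    specificity, accuracy, good detection rate and error rate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    graphics,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    e1071,
    optparse
Config/testthat/edition: 3
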