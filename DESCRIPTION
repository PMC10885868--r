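Package: uncertram
Title: Multi-Annotator Label Uncertainty as Privileged Information for
    Medical Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for training image classifiers when the training labels
    come from a panel of annotators who disagree. Implements ordinal
    annotation encodings (score histogram, histogram plus reviewer
    indicators, per-reviewer score slots), an image-level uncertainty
    measure combining per-score equivocality with inter-rater spread, and
    an uncertainty-gated two-branch privileged-information network in the
    TRAM (Transfer and Marginalize) family with a rank-consistent ordinal
    (CORN) head on the privileged branch. Includes mean-label aggregation,
    pairwise Cohen's kappa agreement matrices, patient-wise cross-validation
    with uncertainty-filtered validation sets, baseline models (linear
    probing, fine tuning, per-annotator confusion-matrix estimation, plain
    TRAM and its thresholded and ordinal variants), uncertainty-stratified
    evaluation with eight test metrics, and a synthetic multi-annotator
    chest-radiograph-like data generator for benchmarking without access to
    protected clinical data. The neural-network layers (strided
    convolutions, batch normalization, Adam) are implemented directly on
    R's linear algebra so the stop-gradient and gating semantics are fully
    inspectable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    png,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
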