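Package: dfbcsp
Title: Discriminative Filter-Bank Common Spatial Patterns for Motor-Imagery EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decoding pipeline for upper-limb motor-imagery
    electroencephalography (EEG). Implements common spatial pattern (CSP)
    spatial filtering, a nine-band discriminative filter-bank extension
    (DFBCSP) with mutual-information sub-band selection, linear support
    vector machine, multilayer perceptron and shrinkage linear discriminant
    classifiers, and a full evaluation suite (stratified cross-validation,
    Cohen's kappa, macro-averaged ROC AUC, t-based confidence intervals,
    repeated-measures ANOVA with Bonferroni-corrected paired t tests, and
    ERD/ERS time courses). Includes a synthetic generator of
    event-related desynchronization/synchronization EEG so the whole
    pipeline can be exercised and validated without access to recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    pROC,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
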