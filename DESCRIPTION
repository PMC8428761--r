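Package: wristrf
Title: Radiofrequency Wrist-Transmission Screening for Low Bone Density
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for radiofrequency-based osteopenia/osteoporosis
    screening from bilateral wrist S-parameter spectra. Provides a cohort data
    model with packed-CSV and Touchstone (.s2p) readers, a synthetic cohort
    generator with group-dependent Lorentzian resonance structure, feature
    assembly (magnitude/phase/complex encodings, age/BMI normalization,
    bilateral arm-combination modes), a two-layer dropout multilayer-perceptron
    classifier with a fixed hidden-width sizing rule, stratified k-fold
    cross-validation with left/right decision fusion, and diagnostic-test
    metrics (sensitivity, specificity, accuracy, Youden's J).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
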