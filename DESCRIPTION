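Package: diatomslide
Title: Virtual-Slide Diatom Classification Pipeline with Synthetic Benchmarks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating taxonomic image classifiers for
    diatom virtual slides. Generates synthetic virtual slides with polygon
    ground truth and two-cohort ("expedition") concept drift, extracts
    labelled object cut-outs with gold-standard label resolution and soft
    background masking, assembles data sets (per-cohort class filters, class
    caps, stratified pooled/cross-validation/out-of-set splits), trains a
    small convolutional classifier with seven-transform augmentation on a
    frozen or trainable backbone, scores predictions with micro- and
    macro-averaged F1 (including the degenerate-class convention), and
    estimates baseline-relative effects of data-set size, background masking
    and out-of-set prediction from a factorial experiment design by ANOVA.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    tiff,
    stats,
    utils
Suggests:
    mgcv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
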