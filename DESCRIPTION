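Package: grimace
Title: Automated Face-Frame Capture and Grimace-Scale Statistics for Rodent Pain Videos
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A desk-scale pipeline for facial-expression pain scoring in
    laboratory rodents. Detects eyes and ears in cage video with boosted
    cascades of Haar-like features, flags frames in which an eye and an ear
    lie within configurable distance bounds, keeps the three least-blurred
    candidates per 3-minute interval (smallest mean absolute pixel difference
    to the previous frame), and exports cropped, blinded, seed-randomized
    still images for human grimace-scale scoring. Ingests the resulting
    score tables and computes inter-rater reliability (two-way intraclass
    correlation coefficients), pain/no-pain signal-detection accuracy,
    per-action-unit difference scores, and half-maximal analgesic dose
    (AD50) estimates with confidence intervals from percent-maximal-effect
    regression on log dose. A synthetic-fixture generator renders stylized
    rodent-face videos, cascade training crops, rating matrices with known
    variance components, and dose-response cohorts with known AD50, so every
    stage is testable against exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    withr,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
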