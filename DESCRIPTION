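Package: vocalarm
Title: Quantitative Structure and Context Specificity of Primate Alarm Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multi-element animal vocalizations,
    developed around the vervet monkey alarm and aggression call system:
    spectral and temporal feature extraction from call waveforms (Wiener
    entropy, spectral quartiles, peak-frequency statistics, dominant
    low-frequency band), unsupervised call-type discovery by BIC-driven
    two-step cluster analysis with silhouette validation, supervised context
    discrimination by linear discriminant analysis with jackknifed
    (leave-one-out) classification, and significance assessment by nested
    permuted discriminant function analysis controlling for caller identity.
    Includes a synthetic-call generator with known ground truth for testing
    and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    withr,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    cluster
Config/testthat/edition: 3
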