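Package: facefuse
Title: Signal Detection, Rating-Scale ROC and Score Fusion for Forensic
    Face-Comparison Proficiency Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for 1-to-1 facial image comparison proficiency
    tests scored on an 11-point ordinal support scale (-5 to +5, 0 =
    inconclusive). Computes per-observer rating-scale ROC curves and AUC with
    the tie-aware rank statistic, signal-detection sensitivity (d-prime) and
    response criterion with log-linear boundary correction, response-scale
    usage and error-by-confidence profiles, observer-by-observer Spearman
    similarity matrices split by trial type with block-agreement summaries,
    and wisdom-of-crowds score fusion by resampled averaging of human and
    machine ratings. Includes a synthetic observer generator (equal-variance
    Gaussian evidence model with controllable sensitivity, bias, confidence
    extremeness, inconclusive use and machine-scorer divergence) so every
    stage is testable without access to confidential test data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
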