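Package: edcrowd
Title: Emergency Department Crowding Scores and Their Diagnostic Evaluation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Computes the four emergency-department (ED) crowding indices
    used in prospective overcrowding studies -- the ED occupancy rate
    (EDOR), the ED Work Index (EDWIN), a modified EDWIN that counts
    planned-referral patients as boarders, and the Work Score -- from
    two-hour period snapshots of census, triage mix, staffing and
    boarding.  Provides the full diagnostic-evaluation pipeline used to
    compare such scores against physician-perceived overcrowding (a
    six-point Likert rating) and against adverse events of ED code
    activations: Spearman rank correlation, ROC/AUC with Hanley-McNeil or
    DeLong confidence intervals, Youden-index cutoff selection, exact
    Clopper-Pearson intervals for sensitivity, specificity, PPV and NPV,
    chi-square association tests, Fleiss' kappa, and a seeded synthetic
    generator of shift-structured ED periods for end-to-end testing and
    calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
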