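Package: moreba
Title: Weighted Whole-Body Ergonomic Risk Scoring (MOREBA), Classic REBA
    and CMDQ Tools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the MOREBA score, a weighted linear composite of 14
    physical workplace risk-factor ratings (posture table scores, coupling,
    contact stress, load, force, activity patterns, vibration, temperature
    and work-rest cycle) with coefficients derived from a structural
    equation model of musculoskeletal strain, and classifies workers into
    four musculoskeletal-disorder risk levels via ROC-derived cutoffs.
    Also provides classic REBA posture-table scoring for comparison,
    Cornell Musculoskeletal Discomfort Questionnaire (CMDQ) scoring, a
    Gaussian-copula synthetic cohort generator matched to published
    exposure marginals and correlations, and a validation pipeline
    (sample-size formula, Mann-Whitney AUC, nearest-to-ideal ROC cutoffs,
    R-squared comparison, measurement-quality indices).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
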