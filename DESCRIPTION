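Package: midpass
Title: Anchor-Based Minimal Important Difference and Patient Acceptable
    Symptom State Estimation for Patient-Reported Outcomes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Estimates interpretability thresholds for patient-reported
    outcome measures from longitudinal cohort data anchored to global
    ratings of change and symptom-state satisfaction. Implements four
    anchor-based minimal important difference (MID) estimators (mean
    change, mean difference of change, ROC optimal cut point, and
    predictive-modelling logistic regression) and two patient acceptable
    symptom state (PASS) estimators (75th percentile and ROC), together
    with anchor-credibility validation via Spearman correlation, DeLong
    and bootstrap confidence intervals for the area under the ROC curve,
    a reproducible synthetic-cohort generator for the numerical rating
    scale (NRS) for pain and the Patient-Rated Wrist/Hand Evaluation
    (PRWHE), and a command-line reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
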