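Package: cucurve
Title: Clinical Utility Curves for Risk Prediction Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs clinical utility (CU) curves, which plot sensitivity
    against the number needed to capture one case (NNCOC, the reciprocal of
    positive predictive value) across all risk-score thresholds, together
    with the model-evaluation workflow that surrounds them: logistic risk
    scoring, C statistics with DeLong and bootstrap comparison, continuous
    net reclassification improvement (NRI), integrated discrimination
    improvement (IDI), and the Hosmer-Lemeshow calibration test. Includes
    seeded synthetic-cohort generators, CSV input/output, plotting in the
    two-panel ROC/CU style, and a command-line interface for single-model,
    two-model, and subgroup analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    withr,
    optparse
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
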