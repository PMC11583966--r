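Package: abxdelegate
Title: Counterfactual Antibiotic Prescribing Policies with Delegation to
    Physicians
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating counterfactual antibiotic prescribing
    policies that combine a machine-learned risk of bacterial urinary
    tract infection with observed physician decisions.  Provides a
    calibrated synthetic generator of initial-consultation cohorts
    (risk prediction, prescription, laboratory outcome, point-of-care
    diagnostics), single-threshold full-automation rules and
    two-threshold delegation rules fitted by constrained minimisation of
    antibiotic use subject to no reduction in treated infections,
    counterfactual outcome accounting with percentile bootstrap
    confidence intervals, and diagnostics for physician private
    information, risk-score calibration and discrimination (ROC/AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
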