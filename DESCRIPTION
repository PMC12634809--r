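Package: uqtriage
Title: Uncertainty-Based Rule-Out Evaluation for Semi-Autonomous AI Diagnosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates semi-autonomous AI diagnostic pathways in which a deep
    ensemble's prediction uncertainty triages patients between autonomous AI
    reading and radiologist reading. Implements the two ensemble uncertainty
    metrics meanUQ (distance of the mean ensemble prediction from 0.5) and
    varUQ (ensemble standard deviation), Youden-index rule-out threshold
    selection, combined-pathway sensitivity and specificity at non-inferior
    specificity operating points, the DeLong comparison of AUROCs, and a
    patient-level permutation test for sensitivity differences. A synthetic
    multicenter cohort generator reproduces the statistical structure of a
    clinically significant prostate cancer (csPCa) detection cohort, so the
    full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
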