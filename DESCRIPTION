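Package: fgf21val
Title: Analytical Validation and Steatosis Diagnostics for a Plasma FGF21 ELISA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analytical and clinical validation of a plasma
    fibroblast growth factor 21 (FGF21) enzyme-linked immunosorbent assay run
    on an automated platform. Implements four-parameter logistic calibration
    with closed-form inverse prediction, intra- and inter-assay precision
    summaries, lower limit of quantification from blank wells, dilution
    linearity and spike recovery statistics, interference and stability
    assessment against the total change limit criterion, blood-collection-tube
    comparison, and a clinical-diagnostics stage (eligibility filtering, FIB-4,
    ultrasound attenuation-based steatosis categories, rank statistics,
    ROC/AUC, and dual rule-out/rule-in threshold selection with likelihood
    ratios). A synthetic-data generator reproduces the validation designs and
    patient cohorts with known ground truth so every stage is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
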