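Package: ctoscore
Title: Operator-CTO Score and Comparator Difficulty Scores for CTO-PCI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the operator-CTO clinical scoring model for percutaneous
    coronary intervention of chronic total occlusions (CTO-PCI), which combines
    nine clinical/angiographic lesion variables with three operator-experience
    credits, and maps the total to a four-level procedural difficulty tier.
    Also computes five published comparator scores (J-CTO, PROGRESS, ORA,
    RECHARGE, CL), generates synthetic procedure cohorts with configurable
    lesion-feature prevalences, operator-group composition and tier-conditional
    technical-success probabilities, and evaluates any score on a cohort:
    Hosmer-Lemeshow calibration after univariate logistic recalibration,
    ROC/AUC discrimination with DeLong confidence intervals, Cohen's kappa for
    inter-rater agreement, tiered success tables, and standard group-comparison
    tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    e1071,
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
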