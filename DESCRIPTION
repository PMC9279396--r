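Package: bopdscreen
Title: Semi-Supervised EHR Screening for Undiagnosed Borderline Personality Disorder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two-step screening of structured electronic health records for
    patients likely to have undiagnosed borderline personality disorder (BoPD).
    Step one is a rule engine that selects a potential-BoPD cohort from flat
    patient/encounter/diagnosis tables using CCSR diagnosis groupings,
    encounter-history requirements and ICD-10-CM exclusion ranges. Step two is
    a semi-supervised classifier: an L1-regularized logistic seed model fit on
    expert chart-review (gold) labels is used to assemble a much larger
    silver-labelled training set, a main model is fit on the silver labels, an
    adjustment model separates likely-BoPD from severe psychotic/substance
    presentations, and the two are combined into a final screening probability.
    Includes stratified chart-review sampling, bootstrap confidence intervals
    for AUROC, accuracy, PPV, sensitivity and specificity, and a synthetic EHR
    generator with planted latent classes so the whole pipeline is testable
    without access to a proprietary EHR database.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
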