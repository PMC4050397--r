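Package: ssiclaims
Title: Claims-Based Identification of CABG Surgical Site Infections
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identification of coronary artery bypass graft (CABG)
    surgical site infection (SSI) cases from aggregated health-insurance
    claims episodes, benchmarked against infection-control surveillance
    as the reference standard. Implements the ICD-9-CM code-list model,
    three criteria-counting classification algorithms (strict, moderate,
    loose) built on six antibiotic-use and utilisation surrogates, a
    stepwise logistic regression model with a Youden-index probability
    cutoff chosen on the ROC curve, and a classification and regression
    tree (CART) grown by Gini improvement with minimal cost-complexity
    pruning selected by cross-validation. Includes a seeded synthetic
    cohort generator that emulates the class-conditional distributions of
    a published CABG cohort, confusion-matrix evaluation with the five
    standard diagnostic accuracy metrics, and a train-on-A/verify-on-B
    experiment pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    rpart,
    withr,
    optparse
Config/testthat/edition: 3
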