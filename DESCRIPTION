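Package: fivea
Title: External Validation Toolkit for the 5A Accidental-Hypothermia Mortality Score
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computes the five-component 5A score (Age, Activities of daily
    living, Arrest, Acidemia, Albumin) for adult accidental-hypothermia
    patients, maps scores to in-hospital mortality probabilities through a
    configurable logistic model, and runs a full external-validation
    analysis: concordance statistic with bootstrap or DeLong confidence
    intervals, Brier score, Nagelkerke R-squared, calibration slope and
    intercept, risk-group calibration tables, locally weighted calibration
    curves, and decision-curve analysis against age-only,
    body-temperature-only, treat-all and treat-none strategies. Includes
    albumin estimation from total calcium, worst-case sensitivity scenarios,
    a chained random-forest imputer for missing predictors, and a
    synthetic-cohort generator that emulates the marginal structure of a
    national hypothermia registry, including an exact mode reproducing a
    published risk-group by outcome contingency table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    knitr
Config/testthat/edition: 3
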