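Package: truemodelsim
Title: Can Performance Measures Identify the Outcome-Generating Model?
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Monte-Carlo simulation framework for clinical risk prediction
    modelling that asks whether the logistic model that actually generated a
    binary outcome (the "true" model) can be distinguished from proxy
    candidate models using conventional model performance measures.
    Provides a scenario-grid simulator with correlated proxy predictors, a
    catalog of named candidate models (noise-augmented, stepwise-AIC
    selected, heuristically shrunken, causal-variable replaced, and the
    flip-coin reference), a panel of 25 discrimination, calibration and
    overall performance measures, and reporting utilities that summarise
    per-replicate differences of each candidate to the true model as mean
    and 95 percent range tables and boxplots.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
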