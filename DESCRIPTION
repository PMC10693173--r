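Package: stepcoach
Title: Personalized Physical-Activity eCoaching with Hybrid Forecasting,
    Classification and Rule-Based Recommendations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for automated physical-activity coaching from wearable
    sensor data. Simulates minute- and day-resolution activity records with
    weekday/weekend structure, labels daily activity levels (sedentary to
    highly active) from steps and MET-equivalent activity minutes, balances
    imbalanced level distributions with ADASYN oversampling, forecasts daily
    step counts by autoregression with walk-forward residual-error
    correction and naive-method prediction intervals, classifies activity
    levels with tuned ensemble models evaluated by accuracy, macro
    precision/recall/specificity/F1 and the Matthews correlation
    coefficient, and generates weekly personalized recommendations from a
    propositional rule base with a mutual-exclusivity guard, exported to an
    RDF knowledge graph with SPARQL query support.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    zoo,
    yaml,
    jsonlite,
    randomForest,
    ranger,
    xgboost,
    rpart
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
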