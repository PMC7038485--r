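Package: hrmood
Title: Emotion Recognition from Wearable Heart-Rate Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recognising emotional state (neutral, happy, sad) from
    heart-rate traces recorded by consumer wrist wearables during
    'neutral + target' stimulus sessions. The pipeline segments each session,
    subtracts the neutral-baseline mean heart rate to remove individual
    differences, extracts a canonical set of 53 time-series features
    (difference statistics, entropy, monotone-run duration/amplitude/slope
    summaries, moving-average statistics), ranks features by nearest-neighbour
    mutual information with the emotion label, and evaluates five classifier
    families (kNN, random forest, decision tree, gradient boosting, AdaBoost)
    under leave-one-out cross-validation with mode-of-ten-runs reporting.
    An emotion-conditioned AR(1) session simulator generates study-scale
    synthetic data so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    randomForest,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
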