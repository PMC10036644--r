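Package: strawyield
Title: Receptacle-Count-Corrected Strawberry Yield Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts end-of-season strawberry yield per plant from
    AI-detected flower receptacle counts. Corrects undercounted
    receptacles with a conjugate beta-binomial model of the detection
    proportion and a beta-negative-binomial posterior predictive of the
    true count, estimates cultivar-specific fruiting probabilities with
    an overdispersion-aware quasi-binomial model under multiple
    imputation of the true counts, and compares nested linear yield
    models by AIC, adjusted R-squared and leave-one-out cross-validated
    mean squared error. Includes COCO-style object-detection evaluation
    metrics (IoU, AP over thresholds 0.50-0.95, mAP) and a synthetic
    greenhouse-trial generator so the full pipeline is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    broom,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
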