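Package: unprofitr
Title: Super Learner Prediction of Health Plan Enrollee Unprofitability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying service-level selection incentives in
    individual health-insurance markets. Derives an individual-level
    unprofitability outcome from Marketplace-style plan payment formulas
    (community-rated premium plus mean-normalized risk-adjustment
    transfers), simulates enrollee cohorts with hierarchical binary
    drug-utilization indicators and heavy-tailed annual costs, and fits a
    super learner ensemble (neural network, lasso, ridge, regression
    tree, and main-terms linear regression crossed with three variable
    sets, including a capped lasso screener with forced inclusion of
    high-cost drug classes). Performance is measured with nested
    cross-validated mean squared error and R-squared, relative
    efficiency, a falsification test against an independent simulated
    outcome, and robust residual diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    Matrix,
    nnet,
    pracma,
    purrr,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
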