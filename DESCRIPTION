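Package: campaignimpact
Title: Counterfactual Impact Analysis of Online Health-Awareness Campaigns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how engaging with an online health-awareness campaign
    changes users' subsequent language relative to a control cohort. Provides an
    event-aligned pipeline over timestamped post streams: campaign-engagement
    detection and before/after cohort construction, name-based gender inference,
    lexicon (LIWC-dialect) category scoring into daily rate series, a structural
    time-series counterfactual estimator (local level plus control covariate,
    Kalman-filter maximum likelihood with simulated predictive intervals and
    tail-area p-values, Bonferroni control across categories), campaign reach
    statistics with retweet-network community detection, and gendered
    odds-ratio vocabulary contrasts. Includes a synthetic corpus generator with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
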