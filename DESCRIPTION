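Package: sjstar
Title: STAR Composite Responder Index for Sjogren's Syndrome Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the STAR (Sjogren's Tool for Assessing Response)
    composite responder index for primary Sjogren's syndrome randomised
    controlled trials, together with the evaluation machinery used to
    develop composite endpoints of this kind: parameterised candidate
    endpoint designs (SRI-like, domain-count, point-sum, ACR-like and
    CRESS-like families), between-arm discrimination metrics (concordance
    index, Cohen's d with noncentral-t confidence intervals, Hedges' g),
    random-effects meta-analysis (Mantel-Haenszel, Paule-Mandel tau-squared,
    Q-profile intervals), virtual-twins subgroup discovery, and a synthetic
    two-visit trial simulator with configurable per-domain treatment
    effects for endpoint calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    rpart,
    randomForest,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
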