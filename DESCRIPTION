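Package: cmamnr
Title: Re-Classifying Non-Response to Community-Based Wasting Treatment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pooled-analysis pipeline for longitudinal anthropometry from
    community-based management of acute malnutrition (CMAM) programmes.
    Computes WHO-style LMS z-scores, applies plausibility and longitudinal
    cleaning rules, re-classifies exit outcomes for defaulters and unknowns,
    splits non-responders into high- and low-growth subgroups at the first
    quartile of admission-to-exit anthropometric gain, fits penalized-spline
    mixed growth curves per response group, and models predictors of response
    category with three-category multinomial logistic regression (Wald tests,
    VIF screening, accuracy and multiclass AUC). Includes a synthetic cohort
    generator with planted latent growth classes so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stats,
    mgcv,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    nnet,
    pROC,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
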