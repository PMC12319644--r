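Package: intersmoke
Title: Resampling-Based Identification of Relevant Intersections in
    Smoking Cessation Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for identifying relevant
    intersections (interactions among demographic and socio-economic
    covariates) for two smoking-cessation outcomes in cross-sectional
    survey data: a three-category motivation-to-stop outcome modelled by
    multinomial logistic regression and a binary past-year quit-attempt
    outcome modelled by binary logistic regression.  Provides a synthetic
    survey-data generator with a missing-at-random missingness mechanism,
    chained-equations multiple imputation with Rubin's-rule and
    Meng-Rubin likelihood-ratio pooling, restricted cubic spline bases
    with odds-ratio contrasts, bootstrap out-of-bag model selection by
    scoring rules (polytomous discrimination index, Brier score),
    backward elimination under BIC, the Brant proportional-odds
    diagnostic, marginal predicted-probability surfaces and external
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nnet,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
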