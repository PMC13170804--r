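Package: riverch4
Title: Upscaling Methane Emissions from Nutrient-Enriched Rivers
Version: 0.1.0
Authors@R:
    person("Riverine", "Biogeochemistry Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for estimating riverine methane (CH4) emissions
    from nutrient-enriched, human-impacted rivers. Provides driver screening by
    standardized (Z-score) regression, monthly three-learner ensembles (random
    forest, gradient-boosted trees, support-vector regression) predicting CH4
    concentration and diffusive flux from terrestrial and aquatic predictors,
    grid-cell upscaling with Strahler-order river-area extrapolation, dry/ice
    masking and diffusive-to-ebullitive flux partitioning, and counterfactual
    nutrient-reduction scenarios with mitigation accounting. A synthetic-data
    generator with a known ground-truth response surface makes every stage
    testable by parameter recovery without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    quadprog
Config/testthat/edition: 3
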