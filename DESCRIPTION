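Package: jsyimpact
Title: Two-Stage Bayesian Assessment of Cash-Transfer Impact on District Maternal Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating district-level maternal mortality ratio (MMR)
    trajectories from heterogeneous, biased administrative and survey sources,
    and for assessing the association between MMR and exposure to the Janani
    Suraksha Yojana (JSY) conditional cash-transfer program. Stage one fits a
    Bayesian hierarchical negative-binomial model with district/division/state
    nesting, linear and smooth non-linear time trends, and source-specific
    reporting effects, producing posterior MMR surfaces. Stage two fits a
    multilevel regression of log-MMR on program exposure to each posterior draw
    and pools coefficients across draws with Rubin-style rules, reporting fixed
    effects and district-specific random slopes. Includes multi-source data
    harmonization (envelope benchmarking, survey-based correction of
    over-reported delivery proportions), leave-one-out predictive validation
    via conditional predictive ordinates, and a synthetic-data generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    lme4,
    rjags,
    coda,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
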