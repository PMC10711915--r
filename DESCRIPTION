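Package: levyeval
Title: Controlled Interrupted Time Series Evaluation of the UK Soft
    Drinks Industry Levy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate changes in household purchasing of soft
    drinks around the announcement (March 2016) and implementation
    (April 2018) of the UK Soft Drinks Industry Levy (SDIL).  Classifies
    products into levy tiers and exempt categories, aggregates weighted
    household purchase panels into weekly per-household series, fits
    controlled interrupted time series models with
    autocorrelation-robust uncertainty, and reports absolute and
    relative changes versus counterfactual with delta-method confidence
    intervals.  Includes a seeded synthetic panel generator with known
    ground-truth intervention effects so the whole pipeline can be
    exercised and validated without proprietary market-research data.
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
    glue,
    jsonlite,
    nlme,
    purrr,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
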