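Package: marketce
Title: Savings-Ordered Market Entry Analysis for High-Cost Therapies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Marginal cost-effectiveness tools for deciding the order in which
    an expensive new therapy should take over the market shares of existing
    regimens, developed around the hepatitis C virus genotype 1 case of an
    interferon-free combination entering a single-payer market. Provides Monte
    Carlo simulation of direct therapy cost per sustained virological response
    (SVR) from published cost and efficacy ranges, savings-per-SVR comparison
    of the entrant against each rival by patient subgroup, tiered takeover
    scenarios ordered by projected savings, budget impact analysis, percent of
    patients successfully treated, expenditure per SVR, and incremental
    cost-effectiveness ratios, all under common random numbers with fully
    reproducible seeding. Includes a built-in fixture encoding the Croatian
    payer case study inputs and a synthetic input generator for testing.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
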