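Package: plycost
Title: Static Microsimulation of the Indirect Costs of Arthritis Through
    Lost Productive Life Years
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A static microsimulation pipeline projecting the indirect
    costs of arthritis (lost income, extra welfare payments, lost
    taxation revenue and lost GDP) for the Australian population aged
    45-64 from 2015 to 2030. Provides a synthetic survey and donor-pool
    generator emulating the structure of confidential household survey
    and tax-transfer microdata, exact-cell (hot-deck) donor imputation of
    weekly income, welfare and tax on ten matching variables,
    generalized-regression (GREG/GREGWT-style) calibration reweighting to
    projection-year benchmarks, uprating of monetary amounts in real 2013
    Australian dollars, weighted quantile-regression median gaps with
    bootstrap confidence intervals, national productivity-cost
    aggregation over counterfactual labour-force destinations, and
    GDP-loss attribution for missing workers.
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
    MASS,
    purrr,
    quantreg,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
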