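Package: rootcea
Title: Markov Cost-Effectiveness Analysis of Root Caries Management
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tooth-level Markov cohort modelling for the economic evaluation
    of topical strategies against high-risk root caries. Compares semiannual
    38% silver diamine fluoride (SDF) application with 5% sodium fluoride
    (NaF) varnish over a 19-year horizon: deterministic base-case evaluation
    (discounted costs, extraction-free tooth-years, incremental
    cost-effectiveness ratio, net monetary benefit), one-way sensitivity
    analysis over cost parameters, and probabilistic sensitivity analysis
    with beta/gamma parameter distributions and cost-effectiveness
    acceptability curves. Includes a microsimulation cross-check, a
    synthetic parameter generator, and a calibration routine that fits
    transition probabilities to published base-case outputs.
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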