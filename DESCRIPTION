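Package: urocea
Title: Trial-Based Cost-Utility Analysis and Markov Modelling for
    Urethral Stricture Surgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the economic evaluation of surgical treatments for
    recurrent bulbar urethral stricture (open urethroplasty versus
    endoscopic urethrotomy). Provides a synthetic two-arm trial data
    generator with a recorded ground truth, patient-level micro-costing
    with consumer-price-index conversion to a common price year,
    EQ-5D-5L utility scoring against a pluggable tariff with
    area-under-the-curve QALY construction, a within-trial cost-utility
    analysis (seemingly unrelated regression of costs and QALYs,
    ICER/dominance classification, stratified bootstrap with
    cost-effectiveness acceptability curves, and multiple imputation by
    chained equations with Rubin's rules), and a three-state cohort
    Markov model over a ten-year horizon with deterministic scenario and
    probabilistic sensitivity analyses.
License: MIT
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
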