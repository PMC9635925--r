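Package: mrgscreen
Title: Analysis of Paired High-Throughput Agonist Screens Against MRGPRX2
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing cell-based high-throughput screens for
    G-protein coupled receptor agonists, built around the paired wild-type /
    loss-of-function-mutant design used to find MRGPRX2-selective compounds.
    Provides signal-to-background ratio computation, B-score plate
    normalization by two-way median polish with MAD scaling, hit calling at a
    multiple of the library standard deviation, paired differential selection
    between genotypes with percent-change scoring, ECFP4/Tanimoto
    sphere-exclusion (Butina) clustering of hit structures, four-parameter
    logistic dose-response fitting with EC50 comparison, and percent-release
    degranulation statistics with Sidak-adjusted two-way ANOVA contrasts.
    Includes a synthetic screen generator with known ground truth for
    validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    generics,
    ggplot2,
    stats,
    utils,
    minpack.lm,
    emmeans,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
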