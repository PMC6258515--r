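Package: smaup
Title: Sensitivity of Areal Variables to the Modifiable Areal Unit Problem
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Nonparametric testing of whether a spatially intensive areal
    variable (a rate, density or proportion) keeps its distributional
    characteristics when its areas are aggregated into fewer contiguous
    regions. Implements the S-maup statistic, its tabulated Monte-Carlo
    critical values and pseudo-p values, spatial autoregressive (SAR)
    lattice simulation with controlled autocorrelation, rank-matching
    redistribution to retarget autocorrelation, seed-based random
    contiguous regionalisation with mean dissolve, relative-change
    effect metrics with Levene and Welch tests, empirical null
    distribution generation, power and size experiments, a reduced-scale
    recalibration pipeline for the statistic's fitted constants, and a
    k-scan that finds the maximum safe aggregation level. A thin command
    line interface is included.
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
    Matrix,
    methods,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    car,
    igraph,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
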