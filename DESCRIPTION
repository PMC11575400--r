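Package: crossfeedr
Title: Growth Kinetics, Mutation Parallelism and Invasion Analysis for
    Cross-Feeding Microbial Evolution Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational core of serial-transfer evolution
    experiments with cross-feeding bacterial communities. Estimates Monod
    resource-use traits (maximum growth rate, yield, maximum uptake rate and
    half-saturation constant) from plate-reader optical-density curves via a
    multistep procedure; tests trait distributions for differences and for
    bimodality with a from-scratch Hartigan dip statistic; computes gene-level
    mutation-parallelism Poisson tests, non-synonymous/synonymous ratios and
    sweep classifications from mutation tables (tidy TSV or a minimal
    GenomeDiff subset); derives Malthusian parameters and selection rate
    constants from reciprocal invasion assays; and simulates two-species
    commensal communities under daily serial transfers to generate synthetic
    data with the statistical structure the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    quadprog,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
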