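Package: dotlattice
Title: Efficient Bayesian Observer Simulations for Multistable Dot Lattices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates a hierarchical efficient Bayesian observer of
    orientation perception in multistable dot lattices, producing attractive
    (hysteresis) and repulsive (adaptation) temporal context effects from a
    single coherent model. Provides circular (axial, period-180) von Mises
    machinery, efficient-coding stimulus-to-sensory mappings derived from
    cumulative frequency distributions, two-stage trial-level predictions for
    rectangular and hexagonal lattices, model-variant ablations, experiment
    and population simulation with a truncated multivariate normal over
    individual parameters, and per-individual binomial-GLM estimation of
    proximity, adaptation and hysteresis effects with bootstrap correlation
    intervals.
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
    MASS,
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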