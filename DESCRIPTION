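Package: ecdnasim
Title: Spatial Stochastic Simulation and Inference of ecDNA Copy-Number
    Dynamics in Growing Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the somatic evolution of extrachromosomal DNA (ecDNA)
    in expanding tumor cell populations. Tumors grow on a two-dimensional
    lattice by rejection-free kinetic Monte Carlo with cell pushing, random
    binomial segregation of ecDNA at division, and a constant-selection
    fitness model; a non-spatial Gillespie engine covers the well-mixed
    limit. Circular core, infiltrating-margin, and leading-edge regions are
    sampled from simulated tumors to emulate multiregion DNA FISH counts,
    and approximate Bayesian computation with the first Wasserstein distance
    infers the initial ecDNA copy number, selection strength, and spatial
    pushing range from observed per-cell copy-number distributions.
    Extensions cover wild-type/variant ecDNA heteroplasmy and two
    cosegregating, coselected ecDNA species.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
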