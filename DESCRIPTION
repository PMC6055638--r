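Package: ddlocal
Title: Local Diversity-Dependent Diversification: Simulation and Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stochastic simulation of clade diversification in two regions
    connected by dispersal, where sympatric speciation and dispersal are
    diversity-dependent, allopatric speciation splits widespread species, and
    local extinction is constant.  Reconstructs extant-species phylogenies
    from event histories, computes crown-conditioned likelihoods of branching
    times under constant-rates and diversity-dependent birth-death models via
    a hidden-state master equation, fits both models by maximum likelihood,
    and detects diversity-dependence with a parametric bootstrap likelihood
    ratio test.  Includes species- and lineages-through-time summaries and a
    scenario grid for power, type-I-error and parameter-bias studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    parallel,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
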