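Package: paleodiv
Title: Paleoenvironment-, Trait- and Diversity-Dependent Diversification on
    Time-Calibrated Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Birth-death diversification analysis for ultrametric phylogenies
    of rapid radiations, centred on Andean-type mountain clades. Implements
    maximum-likelihood fitting and model selection (AICc, likelihood-ratio
    tests) for time-inhomogeneous birth-death models whose speciation and/or
    extinction rates track a smoothed paleoenvironmental covariate such as
    Andean paleoelevation or a Cenozoic temperature proxy; the binary-state
    speciation-extinction (BiSSE) likelihood with state-specific sampling
    fractions, constrained model lattices and Metropolis MCMC; Pagel-style
    correlated-evolution tests for binary trait pairs; diversity-dependent
    speciation with carrying-capacity estimation via a hidden-lineage master
    equation; a fixed-shift two-regime birth-death comparison; and the
    closed-form Magallon-Sanderson crown-group net-diversification estimator
    used to rank rapid radiations. A simulation module generates ultrametric
    trees under every fitted model (including Poisson-thinned time-varying
    rates and joint trait-tree simulation), incomplete-sampling schemes,
    template paleoenvironment curves, and trait tables, so that every
    analysis is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
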