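Package: modflex
Title: DNA Flexibility and Nucleosome Mechanics of Cytosine Modifications
Version: 0.1.0
Authors@R: person("modflex", "developers", role = c("aut", "cre"),
    email = "modflex@example.org")
Description: Analysis pipeline for the effect of cytosine modifications
    (5-methyl-, 5-hydroxymethyl-, 5-formyl- and 5-carboxyl-cytosine) on DNA
    flexibility and nucleosome mechanical stability. Implements rigid
    base-pair reference-frame fitting and extraction of the twelve intra- and
    inter-base-pair structural parameters, synthetic conformational-ensemble
    generation with CpG-localized modification effects, per-position Gaussian
    fluctuation statistics with block-averaged standard errors, two-state
    single-molecule cyclization kinetics simulation and exponential fitting,
    a Monte Carlo loop-closure propensity estimator for fluctuating
    base-pair chains, and classification and averaging of single-molecule
    FRET force-spectroscopy stretching traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    bio3d,
    data.table,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
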