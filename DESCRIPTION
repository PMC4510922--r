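Package: amoebacsp
Title: Amoeba-Inspired Stochastic Search for Constraint Satisfaction
    and Chemical Reaction Path Exploration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A bounceback-controlled concurrent stochastic search engine
    modelled on the spatiotemporal dynamics of an amoeboid organism, with
    two frontends: a Boolean satisfiability (SAT) solver with a WalkSAT
    baseline and a uniform random 3-SAT benchmark generator, and a
    valence-constraint chemistry explorer that enumerates and stochastically
    visits metastable molecular compositions under octet-rule bounceback
    constraints. Records trajectories, metastable-state dwell times and
    empirical transition statistics.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    optparse,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
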