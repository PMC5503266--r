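Package: moranfix
Title: Exact and Monte Carlo Fixation Probabilities for the Moran Process
    on Graphs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for evolutionary graph theory under birth-death updating:
    exact fixation probabilities of the Moran process on connected undirected
    graphs by solving the absorbing Markov chain over arbitrary-precision
    rationals, symmetry-lumped chains for the ell-graph family, reconstruction
    of the fixation probability as an exact rational function of the fitness
    from interpolation at low-complexity rational points, Sturm-sequence sign
    certification of suppressor/amplifier-of-selection status, embedded-chain
    Monte Carlo estimation with Wilson confidence intervals, and exhaustive
    classification of all connected graphs of small order.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: GNU GMP (libgmp, libgmpxx)
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
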