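Package: wormswarm
Title: Agent-Based Simulation and Inference of C. elegans Aggregation and
    Swarming
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates collective feeding behavior of C. elegans as
    self-propelled worm-like chains in a periodic arena, with
    density-dependent cluster-edge reversals, stochastic switching between
    crawling speeds, medium-range taxis towards neighbors, and local food
    depletion that drives emergent swarming.  Provides the spatial summary
    statistics used to quantify aggregation (pair correlation,
    single-linkage branch-length distribution, positional dispersion and
    kurtosis), trajectory analyses (signed speed, reversal detection,
    density-binned rates with bootstrap, cluster tracking), and rejection
    approximate Bayesian computation over the behavioral parameters.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: Rcpp, stats, utils, graphics, grDevices, jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), yaml, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
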