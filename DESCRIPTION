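Package: chronocv
Title: Penalized-Likelihood Chronograms with Cross-Validated Discrete Clocks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Divergence-time estimation on rooted phylograms under a discrete
    relaxed molecular clock. Node ages are fitted by maximizing a penalized
    Poisson likelihood in which every branch rate belongs to one of k shared
    rate categories and a smoothing weight lambda penalizes rate differences
    between adjacent branches, subject to fossil, geological and secondary
    calibration bounds on node ages. The number of categories and the
    smoothing weight are selected by a terminal-deletion cross-validation
    score based on the predicted crown height of a focal clade. Chronogram
    grids can be run over collections of optimal and bootstrap trees to
    summarize the distribution of the focal clade's time to most recent
    common ancestor. A seeded synthetic-data generator (Yule topologies,
    Markov-switching discrete branch rates, Poisson substitution noise,
    bootstrap-like tree perturbation) provides benchmark instances with
    known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape (>= 5.0),
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
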