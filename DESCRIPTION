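Package: slopeval
Title: Dynamic Grade Evaluation of Slope Ecological Restoration Effect
Version: 1.0.0
Authors@R:
    person("slopeval", "maintainers", email = "slopeval@example.org",
           role = c("aut", "cre"))
Description: Weight-free probabilistic grading of slope ecological
    restoration sites. Sites described by quantitative and ordinal
    condition indexes are compared, by a square-root cosine (Hellinger
    affinity) similarity, against grade-representative index vectors drawn
    uniformly from a five-grade standard; repeating the draw-and-classify
    step over many Monte-Carlo trials yields a grade-probability vector.
    The grade distribution is projected forward in time with a Markov
    chain whose row-stochastic transition matrix is fitted to sparse
    calibration distributions by constrained multi-start optimization,
    with absorbing best/worst grades. Local finite-difference sensitivity
    of the evaluation to each index is included, together with readers and
    writers for the delimited grade-standard, site and calibration
    formats, bundled engineering fixtures, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    optparse,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
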