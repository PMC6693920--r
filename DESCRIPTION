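Package: driftchoice
Title: Bounded Drift-Diffusion and Heuristic Models for Two-Alternative
    Choice and Reaction-Time Data
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for modeling joint choice and reaction-time data from
    two-alternative decision tasks, both value-based (choices between items
    with elicited subjective values) and perceptual (signed color-coherence
    discrimination).  Implements a bounded drift-diffusion model with
    collapsing bounds, a power-law mapping from stimulus strength to drift
    rate, and Gaussian non-decision time; first-passage time densities are
    obtained by numerically propagating the Fokker-Planck equation with fast
    convolution.  Also provides an alternative rule-based ("heuristic")
    choice model, maximum-likelihood fitting by multi-start Nelder-Mead,
    BIC model comparison, psychometric/chronometric summaries, an
    efficiency index, Welch's t-test, task-design generators, and an
    Euler-Maruyama trial simulator that serves as an independent oracle
    for the density solver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
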