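Package: gwalign
Title: Alignment of Untargeted LC-MS Feature Tables with Unbalanced
    Gromov-Wasserstein Optimal Transport
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Matches metabolic features between two untargeted liquid
    chromatography-mass spectrometry (LC-MS) studies without shared samples
    or known landmarks. Features are aligned by comparing the intra-study
    distance structure of their intensity profiles through entropically
    regularized unbalanced Gromov-Wasserstein optimal transport, restricted
    to mass-to-charge compatible pairs. The soft coupling is refined by a
    weighted B-spline estimate of the retention-time drift between studies
    with prediction-interval and median-absolute-deviation outlier
    filtering, then reduced to a one-to-one partial matching. Includes a
    simulation framework that splits a base feature table into two noisy
    overlapping studies with known ground truth, and precision/recall
    benchmarking utilities with Wilson score intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    splines,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
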