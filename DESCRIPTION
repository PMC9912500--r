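Package: effectpath
Title: Effect-Type Classification for Risk-Factor Adjustment in Selection-Sampled Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether regression adjustment for an outcome
    risk factor in a selection-sampled dataset (for example a dataset comparing
    immigrants with non-immigrants, where inclusion is restricted to S = 1)
    estimates a total effect, a controlled direct effect, or a biased quantity.
    Provides a causal directed acyclic graph engine (path enumeration,
    d-separation with selection conditioning, and an effect-type classifier),
    linear-Gaussian structural causal models with logistic selection for
    simulating full origin populations and their selected subsamples,
    do-intervention ground truths (analytic and Monte Carlo), regression and
    inverse-probability-weighted estimators with replicate-level bias
    quantification, and pre-built experiments that check every qualitative
    classifier verdict against simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    sandwich,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
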