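Package: peakscape
Title: Macroevolutionary Adaptive Landscapes from Chronograms and Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative-phylogenetics workflow for inferring the adaptive
    landscape of continuous traits on time-calibrated phylogenies.
    Implements phylogenetic (GLS) size correction and phylogenetic
    principal components analysis with a permutation test for critical
    axes; exact likelihoods and maximum-likelihood fitting of Brownian
    motion, single-peak Ornstein-Uhlenbeck, early-burst, and multi-regime
    Hansen models; a stepwise forward/backward adaptive-peak (SURFACE-style)
    regime search with a Brownian-motion null distribution for its peak
    statistics; trait simulators; and disparity-through-time analyses with
    the morphological disparity index and posterior-predictive model
    checks, replicated over posterior sets of chronograms. Includes a
    synthetic-data generator emulating the study design so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    phytools,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
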