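Package: handevo
Title: Phylogenetic Comparative Analysis of Primate Hand Proportions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Morphometric and phylogenetic comparative tools for studying the
    evolution of hand-length proportions in anthropoid primates. Computes
    intrinsic (thumb-to-digit) and extrinsic (body-size-standardized) hand
    proportions from specimen-level measurements, estimates body mass from
    femoral head diameter by allometric regression, and summarizes shape
    variation by covariance-matrix principal components. On a time-calibrated
    phylogeny (with fossil tips grafted via ghost lineages) it fits Brownian
    motion and multi-regime Ornstein-Uhlenbeck (Hansen) models, detects
    adaptive-regime shifts and convergence by a stepwise AICc search (forward
    shift addition, backward regime collapse), compares evolutionary
    hypotheses by Akaike weights, reconstructs ancestral states by maximum
    likelihood with confidence intervals for phylomorphospace projection, and
    measures phylogenetic signal with Blomberg's K and its permutation test.
    Includes generators for synthetic specimen-level datasets with the
    clade-structured regime signal the methods are designed to detect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phytools,
    withr
Config/testthat/edition: 3
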