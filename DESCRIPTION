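Package: ctscore
Title: Checkerboard and Togetherness Co-Occurrence Analysis for Binary
    Community Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Randomization-based analysis of pairwise species
    co-occurrence in binary community matrices, built around the
    checkerboard (C) and togetherness (T) scores of Stone & Roberts.
    Provides read-count filtering and binarization of OTU tables,
    margin-preserving (fixed-fixed) null models via the curveball
    trade algorithm with an exact enumeration oracle, per-pair and
    community-level randomization tests with false discovery rate
    control, host-contrast permutation tests, supporting diversity and
    spatial statistics (sample-based rarefaction, Raup-Crick
    dissimilarity, Mantel correlograms, Moran's I, PERMANOVA, PERMDISP,
    CLAM classification), and a synthetic community generator with
    planted pairwise odds-ratio couplings for method validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    vegan,
    ape,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
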