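Package: morphodelim
Title: Model-Based Morphometric Species Delimitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for statistical delimitation of operational taxonomic
    units (OTUs) from continuous morphometric measurements. Implements a
    constrained-covariance Gaussian mixture engine (the 14 eigen-decomposed
    covariance families) with EM fitting and BIC model selection;
    unsupervised inference of the number of morphological clusters;
    supervised (EDDA) discriminant fitting with a greedy BIC-guided merge
    path over delimitation schemes; explicit taxonomic hypothesis testing
    via Bayes factors and flat-prior posterior model probabilities;
    shadow-feature random-forest identification of diagnostic characters;
    Thorpe allometric size correction; summary statistics, univariate
    tests, PCA, DAPC and permutational MANOVA; and seeded synthetic-data
    generators exercising the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    MASS,
    ranger,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    vegan
Config/testthat/edition: 3
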