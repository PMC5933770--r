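Package: truncpath
Title: Pathogenicity Prediction for Truncating Protein Variants
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies frameshift and nonsense (truncating) protein variants
    as disease-associated or neutral. Builds feature vectors from the protein
    sequence, a predicted C-alpha structural model, a position-wise
    conservation profile and gene-level annotations; scores variants with a
    from-scratch gradient-boosted regression-tree ensemble trained as a pair
    of class-balanced models; evaluates with homology-clustered
    cross-validation; and calibrates scores into p-values by fitting an
    extreme-value (Gumbel) null to neutral score histograms, with an
    exome-level false-discovery-rate estimator. Includes a synthetic cohort
    generator with planted signal so the full pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    Biostrings,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    xgboost,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
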