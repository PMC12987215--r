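Package: craniomorph
Title: Marker-Based Infant Head Point Clouds, Semi-Synthetic Augmentation
    and Cranial Deformity Classification Benchmarks
Version: 0.1.0
Authors@R:
    person("Craniomorph", "Developers", email = "craniomorph@example.org",
           role = c("aut", "cre"))
Description: Tools for processing marker-cap three-dimensional infant head
    scans: a parametric generator of synthetic marker clouds for six cranial
    shape classes (normocephaly, brachycephaly, dolichocephaly, plagiocephaly,
    towering and trigonocephaly), a fiducial-sticker reference frame and basic
    cranial anthropometry, semi-synthetic cohort expansion by constrained
    similarity scaling and bounded marker noise, extraction of 138
    origin-to-marker mean-distance descriptors, and a reproducible
    classification benchmark comparing a CART decision tree, a random forest
    and a multilayer perceptron under randomized and exhaustive hyperparameter
    searches with stratified or grouped train/validation/test splits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
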