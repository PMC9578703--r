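Package: urbancanopy
Title: Diversity, Spatial Structure and Biotic Homogenization of City Tree
    Inventories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing standardized municipal street-tree
    inventories as ecological communities: Hill-number diversity (effective
    species counts) with Monte-Carlo standardization to a common population
    size, Santamour 10/20/30 abundance checks, density-based spatial
    clustering of trees (HDBSCAN) with a bootstrap null model for
    clustering-by-species, chi-square community similarity with subsampling
    standardization, nativity coding against state reference floras,
    grid-based spatial-coverage audits, and a synthetic-city generator so
    every stage can be exercised against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    optparse,
    yaml
Config/testthat/edition: 3
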