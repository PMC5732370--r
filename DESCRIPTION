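Package: spcatest
Title: Eigenvalue Permutation Tests for Spatial Principal Component
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Spatial principal component analysis (sPCA) of allele
    frequency data with a Monte-Carlo eigenvalue test for global and
    local spatial genetic structure.  Positive sPCA eigenvalues carry
    positively autocorrelated ('global') patterns such as clines and
    patches, negative eigenvalues carry negatively autocorrelated
    ('local') patterns.  The test compares cumulative sums of observed
    eigenvalues with their permutation null distributions, then selects
    significant axes with a sequential Bonferroni cascade.  Includes a
    structured-coalescent SNP simulator (island, stepping-stone and
    lattice isolation-by-distance migration), spatial-pattern generators
    and a power-study harness for type-I-error and power benchmarking.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
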