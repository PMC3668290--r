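Package: qmbmdr
Title: Quantitative Model-Based Multifactor Dimensionality Reduction for
    Epistasis Screening
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Exhaustive two-locus epistasis screening for quantitative
    traits with Model-Based Multifactor Dimensionality Reduction (MB-MDR).
    Each SNP pair's nine multilocus genotype cells are labeled High, Low or
    Other by cell-versus-rest association tests (pooled-variance Student's t
    or Welch's unequal-variance t), pooled labels are re-tested against the
    remainder, and the per-pair maximum F statistic is corrected for
    multiple testing with the Westfall-Young step-down maxT permutation
    procedure. Includes pre-analysis trait transformations (log,
    standardization, rank, rank-to-normality), a two-locus pure-epistasis
    checkerboard (M170) trait simulator with normal, chi-square and
    Student-t residual scenarios under homo- or heteroscedasticity, and a
    study harness estimating familywise error, false-positive rates and
    power over the full simulation grid.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
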