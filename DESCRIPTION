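Package: pleioscan
Title: Fast Sequential Testing for Pleiotropic Loci in Multi-Trait GWAS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-trait genome-wide association scans with a fast sequential
    Wald intersection-union test for pleiotropy. Per-SNP effects across traits
    are estimated by generalized least squares (seemingly unrelated
    regressions) with a covariate-adjusted-phenotype approximation of the
    error covariance, so the covariance is estimated once rather than per
    SNP. Incomplete phenotype records are handled by grouping samples by
    missing-value pattern and combining group-wise sufficient statistics.
    Includes a PLINK bed/bim/fam reader and writer, a Monte Carlo engine for
    type-I error and power studies (with a compiled sufficient-statistic
    sampler for large replicate counts), a synthetic fixture generator, and
    post-GWAS utilities that merge significant SNPs into non-overlapping
    genomic regions and tabulate trait sharing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
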