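Package: forensimpute
Title: Genotype Imputation Benchmarking for Forensic SNP Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-based benchmarking of SNP-to-SNP genotype imputation
    under forensic conditions. Generates phased haplotype reference panels
    with tunable linkage disequilibrium and population structure, degrades
    complete diploid genotype sets the way forensic samples degrade (random
    pruning, allelic drop-in and drop-out), imputes missing genotypes with a
    diploid Li-Stephens haplotype-copying hidden Markov model, calls imputed
    genotypes at a genotype-probability threshold, and scores call rate and
    error rate across a configurable design matrix with median/min/max
    aggregation over replicate samples. Panels, degraded samples, and imputed
    results round-trip through standard VCF.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
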