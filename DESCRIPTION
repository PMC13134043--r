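Package: mtclimscan
Title: Genotype-Environment Association Scans for Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide climate-association scans on non-recombining
    genomes such as human mitochondrial DNA. Implements iterative curation of
    gapped multi-sequence alignments, binary variant extraction with haploid
    VCF output, minor-allele-frequency and per-country sample filters,
    principal-component summaries of shared ancestry, a binomial
    random-intercept mixed-model engine (Laplace approximation with an
    adaptive Gauss-Hermite oracle), per-SNP likelihood-ratio scans with
    Bonferroni control, candidate clustering by genotype correlation,
    competitive assignment of paleo-bioclimatic predictors, and a simplified
    phylogenetic subsequent test with a homoplasy-matched null. A coalescent
    simulator with recurrent mutation, clade-biased country assignment,
    correlated climate predictors and injectable selection provides ground
    truth for calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    igraph,
    jsonlite,
    minqa,
    pracma,
    stats,
    tools,
    utils,
    withr,
    yaml,
    Biostrings
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    lme4,
    vcfR,
    phangorn
Config/testthat/edition: 3
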