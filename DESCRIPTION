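Package: qtlwin
Title: Bayesian Mixture-Model GWAS with Sliding-Window QTL Region Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide association analysis for weighted corrected phenotypes
    in pedigreed populations. Implements a single-SNP weighted linear mixed
    model scan with a pedigree polygenic effect (two-stage generalised least
    squares with exact REML variance components), a Bayesian two-component
    normal mixture model for all SNP effects fitted by Gibbs sampling
    (spike-and-slab style prior with a fixed 100-fold variance ratio and a
    Beta(100, 1) prior on the small-effect probability), and post-MCMC QTL
    region detection from sliding-window posterior probabilities (PP_int).
    Includes marker and animal quality control, naive mean imputation,
    genomic-control inflation factors, a pedigree-based simulator of
    LD-structured genotypes and weighted phenotypes with planted QTL, and an
    end-to-end pipeline over plain-text PLINK-style files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
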