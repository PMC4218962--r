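Package: paleoimpute
Title: Low-Coverage Ancient Genome Imputation and Population Genetic Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing low-coverage ancient human genomes against a
    phased reference panel: post-mortem deamination profiling and endogenous
    content accounting, sex determination from X:Y read counts, mitochondrial
    and X-chromosome contamination estimation, deamination-aware genotype
    likelihoods with flat-likelihood masking of transition sites, a diploid
    Li-Stephens haplotype-copying hidden Markov model for genotype imputation
    with genotype-probability thresholds, downsampling concordance validation,
    Patterson-normalised PCA with per-sample Procrustes projection, runs-of-
    homozygosity detection with a short/long length split, and trait-SNP
    genotyping. Includes a synthetic-data generator emulating ancient-DNA read
    data (Poisson coverage, Phred errors, terminal cytosine deamination,
    modern human contamination) so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    vcfR
Config/testthat/edition: 3
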