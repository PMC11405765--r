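Package: f2qtl
Title: Low-Coverage Genotyping and Developmental QTL Mapping in F2 Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for quantitative trait locus
    mapping of developmental traits in interspecies F2 intercrosses.
    Simulates meiotic recombination, shallow (~1x) allele read counts at
    homozygous-divergent SNPs, and trait architectures with known ground
    truth; calls per-5kb-bin genotypes with a three-state Gaussian hidden
    Markov model on binned allele frequencies and emits recombination
    blocks as pseudo-SNP dosages; extracts segmentation-clock periods from
    oscillatory reporter traces by Morlet continuous wavelet ridge
    analysis; normalizes phenotypes (rank-based inverse normal per batch,
    or batch mean equating); and maps pseudo-SNPs with a
    leave-one-chromosome-out linear mixed model, setting genome-wide
    significance by phenotype permutation and Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
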