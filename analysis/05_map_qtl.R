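#!/usr/bin/env Rscript

# Stage 5 — pseudo-SNP association mapping.
#
# Maps the inverse-normalized clock period against the recombination-block
# dosages with the leave-one-chromosome-out linear mixed model. Genome-wide
# significance is the lowest p-value from 10 phenotype permutations; a
# Bonferroni threshold (0.05 / number of pseudo-SNPs) is the secondary
# line. Writes the Manhattan-ready scan, thresholds and merged loci.

library(f2qtl)

out <- "results/qtl"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- readRDS("results/sim/config.rds")$cfg$seed

traits <- read_traits_tsv("results/traits/traits_normalized.tsv")
geno <- data.table::fread("results/geno/pseudosnps.tsv", data.table = FALSE)
dos <- as.matrix(geno[, -1])
rownames(dos) <- geno$sample

cfg <- readRDS("results/sim/config.rds")$cfg
bins <- bin_table(cfg$layout)
stopifnot(identical(colnames(dos), bins$id))
ps <- structure(list(dosage = dos, bins = bins,
                     monomorphic = apply(dos, 2, function(x) all(x == x[1])),
                     layout = cfg$layout), class = "pseudo_snps")

y <- traits$invnorm[match(rownames(dos), traits$sample)]
stopifnot(!anyNA(y))

ctx <- scan_context(ps)
scan <- scan_with_context(y, ctx)
perm <- permutation_threshold(y, ps, n_perm = 10, seed = seed + 3000L,
                              ctx = ctx)
bonf <- bonferroni_threshold(ncol(ps$dosage))
sig <- call_significant(scan, perm$threshold, bonf)

write_scan_tsv(sig$scan, file.path(out, "association.tsv"))
data.table::fwrite(sig$loci, file.path(out, "loci.tsv"), sep = "\t")
yaml::write_yaml(list(permutation = perm$threshold, bonferroni = bonf,
                      per_perm_min = as.list(perm$per_perm_min)),
                 file.path(out, "thresholds.yaml"))

fits <- attr(scan, "null_fits")
cat("null-model heritability (per LOCO chromosome):",
    sprintf("%.2f", sapply(names(fits), function(cn) {
      f <- fits[[cn]]
      f$sigma_g / (f$sigma_g + f$sigma_e)
    })), "\n")
cat("permutation threshold:", format(perm$threshold, digits = 3),
    "| Bonferroni:", format(bonf, digits = 3), "\n")
cat("significant loci:", nrow(sig$loci), "\n")
if (nrow(sig$loci)) {
  print(sig$loci[, c("chrom", "start", "end", "peak_start", "peak_p",
                     "sig_bonf")])
}
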