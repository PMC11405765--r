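#!/usr/bin/env Rscript

# Stage 6 — score the run against the simulated ground truth.
#
# Re-derives the genotype calls in memory (cheap) and evaluates: per-bin
# genotype accuracy, crossover-breakpoint localization error, and whether
# the mapped locus hits the true QTL bin within 500 kb.

library(f2qtl)

cfg <- readRDS("results/sim/config.rds")$cfg
sim <- simulate_f2_cohort(cfg)   # same seed -> identical cohort
freqs <- bin_allele_counts(sim$counts, sim$panel, cfg$layout)
calls <- fill_missing(decode_genotypes(freqs))

loci <- tryCatch(data.table::fread("results/qtl/loci.tsv", data.table = FALSE),
                 error = function(e) NULL)
ev <- compare_to_truth(calls, sim$truth, loci = loci,
                       qtl_spec = cfg$qtl_spec, hit_dist_bp = 5e5)

cat("genotype accuracy:", sprintf("%.4f", ev$genotype_accuracy), "\n")
cat("breakpoint localization error:",
    sprintf("%.0f bp", ev$breakpoint_error_bp),
    sprintf("(called %d / true %d breakpoints)\n",
            ev$n_breakpoints_called, ev$n_breakpoints_true))
if (!is.null(ev$qtl)) {
  cat("QTL detection:\n")
  print(ev$qtl)
}
yaml::write_yaml(list(genotype_accuracy = ev$genotype_accuracy,
                      breakpoint_error_bp = ev$breakpoint_error_bp,
                      qtl = if (!is.null(ev$qtl)) lapply(ev$qtl, as.vector)),
                 "results/evaluation.yaml")
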