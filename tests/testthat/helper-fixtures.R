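# Shared fixtures: tiny layouts, hand-built call/truth objects, and the
# exhaustive-enumeration decoder used as the Viterbi oracle.

tiny_layout <- function(n_chrom = 1, length_bp = 5e4, bin_size = 5000) {
  genome_layout(stats::setNames(rep(length_bp, n_chrom),
                                paste0("chr", seq_len(n_chrom))), bin_size)
}

# Build a geno_calls object directly from a states matrix (NA = missing bin).
make_calls <- function(states, layout = NULL) {
  if (is.null(dim(states))) states <- matrix(as.integer(states), nrow = 1)
  if (is.null(layout)) layout <- tiny_layout(1, ncol(states) * 5000)
  bins <- bin_table(layout)
  stopifnot(nrow(bins) == ncol(states))
  samples <- sprintf("S%02d", seq_len(nrow(states)))
  dimnames(states) <- list(samples, bins$id)
  miss <- apply(states, 2, function(x) all(is.na(x)))
  structure(list(states = states, missing = miss,
                 filled = matrix(FALSE, nrow(states), ncol(states),
                                 dimnames = dimnames(states)),
                 bins = bins, samples = samples, layout = layout),
            class = "geno_calls")
}

# Build a bin_freq object directly from a frequency matrix.
make_freqs <- function(f, reads = NULL, n_snps = NULL, layout = NULL) {
  if (is.null(dim(f))) f <- matrix(f, nrow = 1)
  if (is.null(layout)) layout <- tiny_layout(1, ncol(f) * 5000)
  bins <- bin_table(layout)
  samples <- sprintf("S%02d", seq_len(nrow(f)))
  dimnames(f) <- list(samples, bins$id)
  if (is.null(reads)) reads <- matrix(10L, nrow(f), ncol(f), dimnames = dimnames(f))
  if (is.null(n_snps)) n_snps <- rep(5L, ncol(f))
  structure(list(f = f, reads = reads, n_snps = n_snps, bins = bins,
                 samples = samples, layout = layout), class = "bin_freq")
}

# Independent decoder: scores every possible state path by brute force.
# Only usable for short chromosomes (3^n paths).
enumerate_viterbi <- function(f, spec = hmm_spec()) {
  n <- length(f)
  paths <- as.matrix(expand.grid(rep(list(0:2), n)))
  ll <- log(spec$init)[paths[, 1] + 1]
  for (t in seq_len(n)) {
    ll <- ll + stats::dnorm(f[t], spec$means[paths[, t] + 1],
                            sqrt(spec$variance), log = TRUE)
    if (t < n) {
      ll <- ll + log(spec$trans)[cbind(paths[, t] + 1, paths[, t + 1] + 1)]
    }
  }
  unname(paths[which.max(ll), ])
}

# Default desk-scale genotyping run shared by several genocall tests.
# Cached per session so the cohort is simulated once.
genotyped_cohort <- local({
  cache <- NULL
  function(n_f2 = 100, seed = 42) {
    if (!is.null(cache)) return(cache)
    cfg <- cross_config(n_f2 = n_f2, seed = seed)
    sim <- simulate_f2_cohort(cfg)
    fr <- bin_allele_counts(sim$counts, sim$panel, cfg$layout)
    calls <- fill_missing(decode_genotypes(fr))
    cache <<- list(cfg = cfg, sim = sim, freqs = fr, calls = calls)
    cache
  }
})

# One full mapping replicate: simulate reads -> HMM genotypes ->
# inverse-normalized phenotype -> LOCO scan -> 10-permutation threshold.
# Returns the significant loci and the true-QTL hit status.
qtl_replicate <- function(seed, n_f2 = 600, pve = 0.15, polygenic_var = 2,
                          residual_var = 8, n_perm = 10, hit_bp = 5e5) {
  qtl <- if (!is.null(pve)) data.frame(chrom = "chr3", bin = 500L, pve = pve)
  cfg <- cross_config(n_f2 = n_f2, qtl_spec = qtl,
                      polygenic_var = polygenic_var,
                      residual_var = residual_var, seed = seed)
  sim <- simulate_f2_cohort(cfg)
  ph <- simulate_phenotypes(sim$truth, cfg)
  fr <- bin_allele_counts(sim$counts, sim$panel, cfg$layout)
  calls <- fill_missing(decode_genotypes(fr))
  ps <- build_pseudosnps(calls)
  y <- inverse_normalize(ph$y, ph$batch)
  ctx <- scan_context(ps)
  sc <- scan_with_context(y, ctx)
  perm <- permutation_threshold(y, ps, n_perm = n_perm, seed = seed + 500,
                                ctx = ctx)
  sig <- call_significant(sc, perm$threshold,
                          bonferroni_threshold(ncol(ps$dosage)))
  hit <- if (is.null(pve)) NA else {
    any(sig$loci$chrom == "chr3" &
          abs(sig$loci$peak_start - 500 * 5000) <= hit_bp)
  }
  list(loci = sig$loci, hit = hit, threshold = perm$threshold)
}

# Simulation + genotyping + scan only (no permutations): for localization
# checks where the threshold machinery is not under test.
qtl_replicate_scan <- function(seed, n_f2 = 600, pve = 0.2) {
  cfg <- cross_config(n_f2 = n_f2,
                      qtl_spec = data.frame(chrom = "chr3", bin = 500L,
                                            pve = pve),
                      polygenic_var = 0, residual_var = 1,
                      batch_effects = c(one = 0), seed = seed)
  sim <- simulate_f2_cohort(cfg)
  ph <- simulate_phenotypes(sim$truth, cfg)
  fr <- bin_allele_counts(sim$counts, sim$panel, cfg$layout)
  calls <- fill_missing(decode_genotypes(fr))
  ps <- build_pseudosnps(calls)
  list(scan = association_scan(inverse_normalize(ph$y, ph$batch), ps),
       truth = sim$truth)
}
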