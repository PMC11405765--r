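#' Three-state Gaussian HMM specification for binned allele frequencies
#'
#' State 0 = homozygous-Cab, 1 = heterozygous, 2 = homozygous-Kaga, with
#' Gaussian emissions on the per-bin Kaga-allele read frequency. The
#' emission means sit at the expected frequencies (0, 0.5, 1); the shared
#' variance defaults to 0.8 — deliberately wide, so single-bin evidence is
#' weak and state changes are driven by run lengths against near-zero
#' transition probabilities, yielding long recombination blocks.
#'
#' @param means emission means for states 0, 1, 2.
#' @param variance shared emission variance (> 0).
#' @param trans_prob off-diagonal transition probability; rows renormalized.
#' @param init initial state probabilities (default Mendelian 0.25/0.5/0.25).
#' @return object of class `hmm_spec`.
#' @export
hmm_spec <- function(means = c(0, 0.5, 1), variance = 0.8,
                     trans_prob = 1e-8, init = c(0.25, 0.5, 0.25)) {
  if (variance <= 0) stop("variance must be > 0")
  if (trans_prob < 0 || trans_prob >= 0.5) stop("trans_prob must be in [0, 0.5)")
  if (length(means) != 3 || length(init) != 3) stop("three states required")
  if (abs(sum(init) - 1) > 1e-8) stop("init must sum to 1")
  P <- matrix(trans_prob, 3, 3)
  diag(P) <- 1 - 2 * trans_prob
  structure(list(means = means, variance = variance, trans = P, init = init),
            class = "hmm_spec")
}

#' Bin allele read counts into per-bin Kaga-allele frequencies
#'
#' Sums reads supporting each parental allele within non-overlapping bins
#' and computes f = kaga / (kaga + cab) per bin. Bins with zero reads are
#' assigned f = 0.5 (uninformative). Bins containing no panel SNPs at all
#' are additionally marked missing: they carry no genotype information and
#' are excluded from HMM decoding.
#'
#' @param counts an `allele_counts` (per-sample, per-site read counts).
#' @param panel the `snp_panel` the counts refer to.
#' @param layout the `genome_layout` defining the bin grid.
#' @return object of class `bin_freq`: matrices `f` and `reads`
#'   (samples x bins), vector `n_snps` (panel SNPs per bin), `bins`,
#'   `samples`, `layout`.
#' @export
bin_allele_counts <- function(counts, panel, layout) {
  stopifnot(inherits(counts, "allele_counts"), inherits(layout, "genome_layout"))
  bins <- bin_table(layout)
  m <- match(panel$chrom, layout$chrom$chrom)
  if (anyNA(m)) stop("panel chromosome absent from layout")
  if (any(panel$pos < 0 | panel$pos >= layout$chrom$length[m])) {
    stop("panel site outside chromosome bounds (layout mismatch)")
  }
  bin_in_chr <- panel$pos %/% layout$bin_size
  offset <- c(0, cumsum(layout$chrom$n_bins))[m]
  site_bin <- offset + bin_in_chr + 1L  # global 1-based bin index
  B <- nrow(bins)

  n <- nrow(counts$kaga)
  rs_k <- rowsum(t(counts$kaga), site_bin)  # one row per bin holding >=1 site
  rs_c <- rowsum(t(counts$cab), site_bin)
  idx <- as.integer(rownames(rs_k))
  kaga_b <- matrix(0, B, n); cab_b <- matrix(0, B, n)
  kaga_b[idx, ] <- rs_k; cab_b[idx, ] <- rs_c
  tot <- t(kaga_b + cab_b)                  # samples x bins
  f <- t(kaga_b) / pmax(tot, 1)
  f[tot == 0] <- 0.5
  n_snps <- tabulate(site_bin, nbins = B)
  dimnames(f) <- dimnames(tot) <- list(counts$samples, bins$id)

  structure(list(f = f, reads = tot, n_snps = n_snps, bins = bins,
                 samples = counts$samples, layout = layout),
            class = "bin_freq")
}

#' Decode per-bin genotype states with the Gaussian HMM (Viterbi)
#'
#' Runs the most-probable-path decoder per sample per chromosome on the
#' binned frequencies. Bins with no panel SNPs are excluded from decoding
#' and left NA (flagged missing); use [fill_missing()] afterwards. A
#' chromosome whose bins are all missing is an error.
#'
#' @param freqs a `bin_freq`.
#' @param spec an `hmm_spec` (default [hmm_spec()]).
#' @return object of class `geno_calls`: integer matrix `states`
#'   (samples x bins, NA = missing), logical vector `missing` (per bin),
#'   logical matrix `filled`, plus `bins`, `samples`, `layout`.
#' @export
decode_genotypes <- function(freqs, spec = hmm_spec()) {
  stopifnot(inherits(freqs, "bin_freq"), inherits(spec, "hmm_spec"))
  bins <- freqs$bins
  miss <- freqs$n_snps == 0L
  n <- nrow(freqs$f)
  states <- matrix(NA_integer_, n, ncol(freqs$f), dimnames = dimnames(freqs$f))
  log_init <- log(spec$init)
  log_trans <- log(spec$trans)
  for (cn in unique(bins$chrom)) {
    bi <- which(bins$chrom == cn)
    use <- bi[!miss[bi]]
    if (!length(use)) stop("chromosome ", cn, " has no informative bins")
    for (i in seq_len(n)) {
      states[i, use] <- viterbi_gauss(freqs$f[i, use], spec$means,
                                      spec$variance, log_init, log_trans)
    }
  }
  structure(list(states = states, missing = miss,
                 filled = matrix(FALSE, n, ncol(states),
                                 dimnames = dimnames(states)),
                 bins = bins, samples = freqs$samples, layout = freqs$layout),
            class = "geno_calls")
}

#' Fill missing genotype bins from neighbouring calls
#'
#' Every missing bin takes the state of the previous called bin on the
#' same chromosome; a run of missing bins at the chromosome start takes
#' the next called bin's state. Filled bins are flagged.
#'
#' @param calls a `geno_calls`.
#' @return the `geno_calls` with no remaining NA states.
#' @export
fill_missing <- function(calls) {
  stopifnot(inherits(calls, "geno_calls"))
  bins <- calls$bins
  st <- calls$states
  fl <- calls$filled
  for (cn in unique(bins$chrom)) {
    bi <- which(bins$chrom == cn)
    sub <- st[, bi, drop = FALSE]
    na <- is.na(sub)
    if (!any(na)) next
    if (any(rowSums(!na) == 0)) stop("all bins missing on chromosome ", cn)
    for (i in which(rowSums(na) > 0)) {
      v <- sub[i, ]
      idx <- which(!is.na(v))
      # previous called bin, else next called bin for leading gaps
      prev <- findInterval(seq_along(v), idx)
      take <- ifelse(prev >= 1, idx[pmax(prev, 1)], idx[1])
      filled_v <- v[take]
      fl[i, bi][is.na(v)] <- TRUE
      st[i, bi] <- ifelse(is.na(v), filled_v, v)
    }
  }
  calls$states <- st
  calls$filled <- fl
  calls
}

#' Exclude samples with poor genome-wide coverage
#'
#' Computes, per sample, the fraction of bins with at least one read and
#' excludes samples below `min_informative_fraction`.
#'
#' @param freqs a `bin_freq` for the cohort.
#' @param min_informative_fraction threshold in `[0, 1]` (default 0.5).
#' @return list `kept`, `excluded` (sample names) and `fraction` (named
#'   per-sample informative fractions).
#' @export
qc_samples <- function(freqs, min_informative_fraction = 0.5) {
  stopifnot(inherits(freqs, "bin_freq"))
  if (min_informative_fraction < 0 || min_informative_fraction > 1) {
    stop("min_informative_fraction must be in [0, 1]")
  }
  if (nrow(freqs$f) == 0) stop("empty cohort")
  frac <- rowMeans(freqs$reads >= 1)
  keep <- frac >= min_informative_fraction
  list(kept = freqs$samples[keep], excluded = freqs$samples[!keep],
       fraction = stats::setNames(frac, freqs$samples))
}

#' Build the pseudo-SNP dosage matrix from filled genotype calls
#'
#' Each 5-kb bin becomes one marker whose dosage is the genotype state
#' (count of Kaga-type alleles, 0/1/2). Columns follow genome order;
#' monomorphic columns are flagged and optionally dropped.
#'
#' @param calls a filled `geno_calls` (single object covering the cohort).
#' @param drop_monomorphic drop columns with no variation (default FALSE).
#' @return object of class `pseudo_snps`: matrix `dosage` (samples x
#'   bins), `bins`, logical `monomorphic`, `layout`.
#' @export
build_pseudosnps <- function(calls, drop_monomorphic = FALSE) {
  stopifnot(inherits(calls, "geno_calls"))
  if (anyNA(calls$states)) stop("calls contain missing states; run fill_missing first")
  dos <- calls$states
  mono <- apply(dos, 2, function(x) all(x == x[1]))
  bins <- calls$bins
  if (drop_monomorphic) {
    dos <- dos[, !mono, drop = FALSE]
    bins <- bins[!mono, , drop = FALSE]
    mono <- mono[!mono]
  }
  structure(list(dosage = dos, bins = bins, monomorphic = mono,
                 layout = calls$layout),
            class = "pseudo_snps")
}

#' Count genotype state changes per chromosome
#'
#' On filled calls, counts adjacent-bin state differences per sample and
#' chromosome — the decoded proxy for crossover events.
#'
#' @param calls a filled `geno_calls`.
#' @return integer matrix samples x chromosomes.
#' @export
count_state_changes <- function(calls) {
  stopifnot(inherits(calls, "geno_calls"))
  if (anyNA(calls$states)) stop("fill missing bins before counting changes")
  bins <- calls$bins
  chroms <- unique(bins$chrom)
  out <- sapply(chroms, function(cn) {
    sub <- calls$states[, bins$chrom == cn, drop = FALSE]
    if (ncol(sub) < 2) return(rep(0L, nrow(sub)))
    rowSums(sub[, -1, drop = FALSE] != sub[, -ncol(sub), drop = FALSE])
  })
  out <- matrix(as.integer(out), nrow = nrow(calls$states),
                dimnames = list(calls$samples, chroms))
  out
}
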