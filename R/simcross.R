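#' Genome layout for binned analyses
#'
#' Describes the chromosomes of a (simulated or real) genome and the
#' non-overlapping bin grid used throughout the pipeline. Bin `k` (0-based)
#' spans `[k*bin_size, (k+1)*bin_size)` in 0-based half-open coordinates.
#'
#' @param chromosomes named numeric vector of chromosome lengths in bp.
#' @param bin_size bin width in bp (default 5000).
#' @return An object of class `genome_layout`.
#' @export
genome_layout <- function(chromosomes, bin_size = 5000) {
  if (is.null(names(chromosomes)) || anyNA(names(chromosomes)) ||
      any(names(chromosomes) == "")) {
    stop("chromosomes must be a named vector of lengths")
  }
  if (any(chromosomes <= 0)) stop("all chromosome lengths must be > 0")
  if (bin_size <= 0) stop("bin_size must be > 0")
  chrom <- data.frame(
    chrom = names(chromosomes),
    length = unname(as.numeric(chromosomes)),
    n_bins = as.integer(ceiling(chromosomes / bin_size)),
    stringsAsFactors = FALSE
  )
  structure(list(chrom = chrom, bin_size = bin_size), class = "genome_layout")
}

#' Default desk-scale genome: 5 chromosomes x 5 Mb, 5-kb bins
#'
#' A 1/100-scale stand-in for a ~700 Mb, 24-chromosome fish genome that
#' preserves the per-bin information content of the real data (~20
#' informative SNPs per 5-kb bin at the default panel density).
#'
#' @export
default_layout <- function() {
  genome_layout(stats::setNames(rep(5e6, 5), paste0("chr", 1:5)), bin_size = 5000)
}

#' Bin table for a genome layout
#'
#' @param layout a `genome_layout`.
#' @return data.frame with one row per bin: `chrom`, `bin` (0-based index
#'   within chromosome), `start`, `end`, `id` ("chrom:start-end").
#' @export
bin_table <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  bs <- layout$bin_size
  out <- do.call(rbind, lapply(seq_len(nrow(layout$chrom)), function(i) {
    nb <- layout$chrom$n_bins[i]
    k <- seq_len(nb) - 1L
    data.frame(
      chrom = layout$chrom$chrom[i],
      bin = k,
      start = k * bs,
      end = pmin((k + 1) * bs, layout$chrom$length[i]),
      stringsAsFactors = FALSE
    )
  }))
  out$id <- sprintf("%s:%d-%d", out$chrom, out$start, out$end)
  rownames(out) <- NULL
  out
}

n_bins_total <- function(layout) sum(layout$chrom$n_bins)

#' Configuration of a simulated F2 intercross
#'
#' Bundles every parameter of the generative model: genome layout, marker
#' density, meiotic crossover rate, sequencing depth and error, cohort
#' size, trait architecture (QTL effects, polygenic background, batch
#' shifts, residual noise), and the seed.
#'
#' Defaults are a desk-scale version of a two-inbred-strain fish cross:
#' crossovers average 0.8 per chromosome per meiosis (fewer than one, as in
#' fish meiotic maps), read depth averages 1 read per panel SNP, and the
#' trait is a clock period in minutes (baseline 58 min, total SD ~3.4 min)
#' measured on two microscopes whose temperature difference shifts one
#' batch by +3.5 min.
#'
#' @param layout a `genome_layout` (default [default_layout()]).
#' @param snp_density expected homozygous-divergent SNPs per bp (default 1/250).
#' @param crossover_mean expected crossovers per chromosome per meiosis.
#' @param depth_mean expected reads per SNP site per sample.
#' @param seq_error per-read probability that the reported allele is flipped.
#' @param n_f2 number of F2 individuals.
#' @param qtl_spec data.frame with columns `chrom`, `bin` (0-based) and
#'   either `beta` (additive effect per Kaga allele, trait units) or `pve`
#'   (target fraction of non-batch phenotypic variance); NULL for no QTL.
#' @param polygenic_var variance of the polygenic genetic background.
#' @param residual_var residual (environmental + measurement) variance.
#' @param batch_effects named numeric vector of additive batch shifts.
#' @param baseline trait intercept (units of the trait).
#' @param seed integer seed.
#' @return An object of class `cross_config`.
#' @export
cross_config <- function(layout = default_layout(),
                         snp_density = 1 / 250,
                         crossover_mean = 0.8,
                         depth_mean = 1.0,
                         seq_error = 0.002,
                         n_f2 = 150,
                         qtl_spec = NULL,
                         polygenic_var = 2.3,
                         residual_var = 7.5,
                         batch_effects = c(scopeA = 0, scopeB = 3.5),
                         baseline = 58,
                         seed = 1L) {
  stopifnot(inherits(layout, "genome_layout"))
  if (snp_density <= 0) stop("snp_density must be > 0")
  if (crossover_mean < 0) stop("crossover_mean must be >= 0")
  if (depth_mean < 0) stop("depth_mean must be >= 0")
  if (seq_error < 0 || seq_error >= 0.5) stop("seq_error must be in [0, 0.5)")
  if (n_f2 < 1) stop("n_f2 must be >= 1")
  if (polygenic_var < 0 || residual_var < 0) stop("variances must be >= 0")
  if (!is.null(qtl_spec)) {
    qtl_spec <- as.data.frame(qtl_spec)
    stopifnot(all(c("chrom", "bin") %in% names(qtl_spec)))
    m <- match(qtl_spec$chrom, layout$chrom$chrom)
    if (anyNA(m)) stop("qtl_spec names an unknown chromosome")
    if (any(qtl_spec$bin < 0 | qtl_spec$bin >= layout$chrom$n_bins[m])) {
      stop("qtl_spec names a bin outside the genome layout")
    }
    if (!("beta" %in% names(qtl_spec)) && !("pve" %in% names(qtl_spec))) {
      stop("qtl_spec needs a 'beta' or 'pve' column")
    }
  }
  structure(list(
    layout = layout, snp_density = snp_density,
    crossover_mean = crossover_mean, depth_mean = depth_mean,
    seq_error = seq_error, n_f2 = as.integer(n_f2), qtl_spec = qtl_spec,
    polygenic_var = polygenic_var, residual_var = residual_var,
    batch_effects = batch_effects, baseline = baseline,
    seed = as.integer(seed)
  ), class = "cross_config")
}

#' Additive effect size needed for a target QTL variance fraction
#'
#' For an F2 dosage x with Var(x) = 1/2 (Mendelian 0.25/0.5/0.25), solves
#' beta^2 * var_dosage = pve/(1-pve) * base_var so that the QTL explains
#' `pve` of the genetic-plus-residual phenotypic variance.
#'
#' @param pve target fraction of variance explained, in (0, 1).
#' @param base_var non-QTL variance (polygenic + residual).
#' @param dosage_var variance of the marker dosage (F2 expectation 0.5).
#' @export
qtl_effect_for_pve <- function(pve, base_var, dosage_var = 0.5) {
  stopifnot(pve > 0, pve < 1, base_var > 0, dosage_var > 0)
  sqrt(pve / (1 - pve) * base_var / dosage_var)
}

#' Simulate the homozygous-divergent SNP panel
#'
#' Places biallelic marker sites uniformly at the configured density. Every
#' site is homozygous for one allele in the Cab-type parent and homozygous
#' for the other in the Kaga-type parent (hence heterozygous in all F1s),
#' which is exactly the informative marker set the genotype caller assumes.
#'
#' @param config a `cross_config`.
#' @return data.frame `chrom`, `pos` (0-based bp), `cab_allele`,
#'   `kaga_allele`, class `snp_panel`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "cross_config"))
  set.seed(config$seed)
  bases <- c("A", "C", "G", "T")
  panel <- do.call(rbind, lapply(seq_len(nrow(config$layout$chrom)), function(i) {
    len <- config$layout$chrom$length[i]
    n <- stats::rpois(1, config$snp_density * len)
    pos <- sort(sample.int(len, min(n, len)) - 1L)
    ci <- sample.int(4, length(pos), replace = TRUE)
    kag <- bases[(ci - 1L + sample.int(3, length(pos), replace = TRUE)) %% 4L + 1L]
    data.frame(chrom = config$layout$chrom$chrom[i], pos = pos,
               cab_allele = bases[ci], kaga_allele = kag,
               stringsAsFactors = FALSE)
  }))
  rownames(panel) <- NULL
  class(panel) <- c("snp_panel", "data.frame")
  panel
}

#' Simulate one meiosis on one chromosome
#'
#' Crossovers are a homogeneous Poisson process along the chromosome
#' (count ~ Poisson(crossover_mean), positions uniform, no interference);
#' the gamete starts from either parental haplotype with probability 1/2
#' and alternates haplotype origin at each crossover.
#'
#' @param chrom_length chromosome length in bp.
#' @param crossover_mean expected crossovers for this chromosome.
#' @return list with `start` (0 = Cab-type haplotype, 1 = Kaga-type) and
#'   `breaks` (sorted crossover positions, bp).
#' @export
simulate_meiosis <- function(chrom_length, crossover_mean) {
  if (crossover_mean < 0) stop("crossover_mean must be >= 0")
  if (chrom_length <= 0) stop("chromosome length must be > 0")
  n_xo <- stats::rpois(1, crossover_mean)
  list(start = sample(0:1, 1),
       breaks = sort(stats::runif(n_xo, 0, chrom_length)))
}

#' Haplotype origin of a gamete at given positions
#'
#' @param gamete a gamete from [simulate_meiosis()].
#' @param pos positions in bp.
#' @return integer vector, 0 (Cab-type) or 1 (Kaga-type) at each position.
#' @export
gamete_origin <- function(gamete, pos) {
  (gamete$start + findInterval(pos, gamete$breaks)) %% 2L
}

#' Simulate an F2 cohort: true genotypes and shallow allele read counts
#'
#' Each F2 genome is the union of two independent F1 gametes (the F1 is
#' heterozygous at every panel site, so a gamete is fully described by its
#' crossover mosaic of the two parental haplotypes). Per-bin true state is
#' the genotype at the bin midpoint. Read counts per panel SNP are
#' Poisson(`depth_mean`); each read draws one of the site's true alleles
#' (each with probability 1/2 at heterozygous sites) and is flipped to the
#' other parental allele with probability `seq_error`.
#'
#' @param config a `cross_config`.
#' @param panel optional precomputed `snp_panel`; simulated from `config`
#'   if omitted.
#' @return list of class `f2_sim` with elements `truth` (class `f2_truth`:
#'   `states` n x B matrix in {0,1,2}, `gametes`, `layout`, `bins`),
#'   `counts` (class `allele_counts`: `cab` and `kaga` n x S matrices,
#'   `sites`, `samples`), and `panel`.
#' @export
simulate_f2_cohort <- function(config, panel = NULL) {
  stopifnot(inherits(config, "cross_config"))
  if (config$n_f2 < 1) stop("n_f2 must be >= 1")
  if (is.null(panel)) panel <- simulate_panel(config)
  set.seed(config$seed + 1000L)
  layout <- config$layout
  bins <- bin_table(layout)
  n <- config$n_f2
  B <- nrow(bins)
  S <- nrow(panel)
  samples <- sprintf("F2_%04d", seq_len(n))

  mid <- (bins$start + bins$end) / 2
  states <- matrix(0L, n, B, dimnames = list(samples, bins$id))
  geno_snp <- matrix(0L, n, S)  # true dosage of Kaga allele per panel site
  gametes <- vector("list", n)

  chr_bins <- split(seq_len(B), bins$chrom)[unique(bins$chrom)]
  chr_snps <- split(seq_len(S), panel$chrom)[unique(bins$chrom)]

  for (i in seq_len(n)) {
    gametes[[i]] <- lapply(seq_len(nrow(layout$chrom)), function(ci) {
      len <- layout$chrom$length[ci]
      list(mat = simulate_meiosis(len, config$crossover_mean),
           pat = simulate_meiosis(len, config$crossover_mean))
    })
    names(gametes[[i]]) <- layout$chrom$chrom
    for (ci in seq_len(nrow(layout$chrom))) {
      cn <- layout$chrom$chrom[ci]
      g <- gametes[[i]][[ci]]
      bi <- chr_bins[[cn]]
      states[i, bi] <- gamete_origin(g$mat, mid[bi]) +
        gamete_origin(g$pat, mid[bi])
      si <- chr_snps[[cn]]
      if (length(si)) {
        geno_snp[i, si] <- gamete_origin(g$mat, panel$pos[si]) +
          gamete_origin(g$pat, panel$pos[si])
      }
    }
  }

  depth <- matrix(stats::rpois(n * S, config$depth_mean), n, S)
  # P(read reports Kaga allele) given true dosage 0/1/2 and flip rate e
  p_kaga <- c(config$seq_error, 0.5, 1 - config$seq_error)[geno_snp + 1L]
  kaga <- matrix(stats::rbinom(n * S, as.vector(depth), p_kaga), n, S)
  cab <- depth - kaga
  dimnames(cab) <- dimnames(kaga) <- list(samples, NULL)

  truth <- structure(list(states = states, gametes = gametes,
                          layout = layout, bins = bins),
                     class = "f2_truth")
  counts <- structure(list(cab = cab, kaga = kaga, sites = panel,
                           samples = samples),
                      class = "allele_counts")
  structure(list(truth = truth, counts = counts, panel = panel),
            class = "f2_sim")
}

#' Simulate quantitative phenotypes on a simulated cohort
#'
#' Trait model: y = baseline + sum_q beta_q * dosage_q + g + batch + e,
#' where g is a polygenic term built from Normal effects on all genome
#' bins and rescaled so its realized variance equals `polygenic_var`,
#' batch is an additive shift (samples split evenly across the declared
#' batches), and e ~ Normal(0, residual_var). QTL rows with a `pve` column
#' are converted to effects with [qtl_effect_for_pve()] against the
#' polygenic + residual variance.
#'
#' @param truth an `f2_truth` from [simulate_f2_cohort()].
#' @param config the `cross_config` used to simulate it.
#' @return data.frame of class `trait_table`: `sample`, `y`, `batch`, and
#'   the realized components `qtl`, `g`, `e`; attribute `pve_realized`
#'   records Var(qtl)/Var(y - batch).
#' @export
simulate_phenotypes <- function(truth, config) {
  stopifnot(inherits(truth, "f2_truth"), inherits(config, "cross_config"))
  set.seed(config$seed + 2000L)
  X <- truth$states
  n <- nrow(X)
  bins <- truth$bins

  qtl <- rep(0, n)
  spec <- config$qtl_spec
  if (!is.null(spec) && nrow(spec)) {
    base_var <- config$polygenic_var + config$residual_var
    for (j in seq_len(nrow(spec))) {
      col <- which(bins$chrom == spec$chrom[j] & bins$bin == spec$bin[j])
      if (length(col) != 1) stop("QTL bin not found in layout")
      beta <- if (!is.null(spec$beta) && !is.na(spec$beta[j])) spec$beta[j]
              else qtl_effect_for_pve(spec$pve[j], base_var)
      qtl <- qtl + beta * X[, col]
    }
  }

  g <- rep(0, n)
  if (config$polygenic_var > 0) {
    u <- stats::rnorm(ncol(X))
    g0 <- as.vector(scale(X, center = TRUE, scale = FALSE) %*% u)
    s <- stats::sd(g0)
    if (s > 0) g <- g0 / s * sqrt(config$polygenic_var)
  }

  batches <- names(config$batch_effects)
  batch <- sample(rep(batches, length.out = n))
  e <- stats::rnorm(n, 0, sqrt(config$residual_var))
  y <- config$baseline + qtl + g + unname(config$batch_effects[batch]) + e

  out <- data.frame(sample = rownames(X), y = y, batch = batch,
                    qtl = qtl - mean(qtl), g = g, e = e,
                    stringsAsFactors = FALSE)
  yin <- qtl + g + e
  attr(out, "pve_realized") <- if (stats::var(yin) > 0)
    stats::var(qtl) / stats::var(yin) else 0
  class(out) <- c("trait_table", "data.frame")
  out
}

#' Simulate an oscillatory reporter intensity trace
#'
#' Generates intensity = baseline + amplitude * exp(envelope_rate * t) *
#' sin(2*pi*t/period) + trend_slope * t + Normal(0, noise_sd), sampled
#' every `interval_min` from 0 to `duration_min` inclusive. Mimics a
#' her7-type segmentation-clock reporter: a decaying oscillation riding on
#' a slow fluorescence trend.
#'
#' @param period_min true oscillation period (min), > 0.
#' @param amplitude oscillation amplitude at t = 0 (a.u.).
#' @param trend_slope linear trend (a.u./min).
#' @param envelope_rate exponential amplitude rate (1/min; negative decays).
#' @param noise_sd additive Gaussian noise SD (a.u.).
#' @param duration_min total duration (min), >= 2 * interval.
#' @param interval_min sampling interval (min, default 10).
#' @param baseline constant offset (a.u.).
#' @return data.frame `time_min`, `intensity`, class `osc_trace`, with
#'   attributes `interval` and `true_period`.
#' @export
simulate_oscillation <- function(period_min, amplitude = 1, trend_slope = 0,
                                 envelope_rate = 0, noise_sd = 0,
                                 duration_min = 600, interval_min = 10,
                                 baseline = 0) {
  if (period_min <= 0) stop("period_min must be > 0")
  if (interval_min <= 0) stop("interval_min must be > 0")
  if (duration_min < 2 * interval_min) stop("duration too short")
  t <- seq(0, duration_min, by = interval_min)
  x <- baseline + amplitude * exp(envelope_rate * t) * sin(2 * pi * t / period_min) +
    trend_slope * t + stats::rnorm(length(t), 0, noise_sd)
  out <- data.frame(time_min = t, intensity = x)
  attr(out, "interval") <- interval_min
  attr(out, "true_period") <- period_min
  class(out) <- c("osc_trace", "data.frame")
  out
}
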