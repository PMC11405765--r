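#' Default pipeline configuration
#'
#' Nested list mirroring the YAML config layout: `seed`, `stages`,
#' `cross` (simulation), `hmm`, `qc`, `traits`, `qtl`. Any subset can be
#' overridden via `run_config()`.
#'
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    stages = list(simulate = TRUE, genotype = TRUE, traits = TRUE,
                  qtl = TRUE, evaluate = TRUE),
    cross = list(
      n_chrom = 5L, chrom_length = 5e6, bin_size = 5000,
      snp_density = 1 / 250, crossover_mean = 0.8, depth_mean = 1.0,
      seq_error = 0.002, n_f2 = 150L,
      polygenic_var = 2.3, residual_var = 7.5, baseline = 58,
      batch_effects = list(scopeA = 0, scopeB = 3.5),
      qtl = list(list(chrom = "chr3", bin = 500L, pve = 0.15))
    ),
    hmm = list(emission_var = 0.8, trans_prob = 1e-8),
    qc = list(min_informative = 0.5),
    traits = list(normalization = "invnorm", reference_batch = "scopeA"),
    qtl = list(n_perm = 10L, alpha = 0.05, qtl_hit_bp = 5e5)
  )
}

#' Load and validate a pipeline configuration
#'
#' @param config a YAML file path or a nested list; missing entries take
#'   the defaults from [default_run_config()].
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(config = NULL) {
  base <- default_run_config()
  user <- if (is.character(config)) yaml::read_yaml(config)
          else if (is.list(config)) config
          else list()
  cfg <- modify_list_deep(base, user)
  # validate every stage's parameters up front, before any stage runs
  stopifnot(cfg$cross$n_chrom >= 1, cfg$cross$chrom_length > 0,
            cfg$cross$bin_size > 0, cfg$cross$n_f2 >= 1,
            cfg$hmm$emission_var > 0,
            cfg$hmm$trans_prob >= 0, cfg$hmm$trans_prob < 0.5,
            cfg$qc$min_informative >= 0, cfg$qc$min_informative <= 1,
            cfg$qtl$n_perm >= 1, cfg$qtl$alpha > 0, cfg$qtl$alpha < 1)
  if (!cfg$traits$normalization %in% c("invnorm", "equate", "none")) {
    stop("traits$normalization must be invnorm, equate or none")
  }
  cross_config_from(cfg)  # errors early on bad simulation parameters
  class(cfg) <- c("run_config", "list")
  cfg
}

# Deep merge of the user config over the defaults. Named sections merge
# recursively; value-like entries — including the QTL list-of-specs and the
# batch_effects map, whose defaults must not leak into a user override —
# are replaced wholesale.
modify_list_deep <- function(base, user) {
  replace_whole <- c("qtl_specs", "batch_effects")
  for (nm in names(user)) {
    named_section <- is.list(user[[nm]]) && is.list(base[[nm]]) &&
      !is.null(names(base[[nm]])) && !is.null(names(user[[nm]])) &&
      all(names(user[[nm]]) != "")
    if (named_section && !nm %in% replace_whole &&
        !(nm == "qtl" && is.null(names(base[[nm]])))) {
      base[[nm]] <- modify_list_deep(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

cross_config_from <- function(cfg) {
  cc <- cfg$cross
  layout <- genome_layout(
    stats::setNames(rep(cc$chrom_length, cc$n_chrom),
                    paste0("chr", seq_len(cc$n_chrom))),
    bin_size = cc$bin_size)
  qtl_spec <- NULL
  if (length(cc$qtl)) {
    qtl_spec <- do.call(rbind, lapply(cc$qtl, function(q) {
      data.frame(chrom = q$chrom, bin = q$bin,
                 beta = if (is.null(q$beta)) NA_real_ else q$beta,
                 pve = if (is.null(q$pve)) NA_real_ else q$pve)
    }))
  }
  cross_config(
    layout = layout, snp_density = cc$snp_density,
    crossover_mean = cc$crossover_mean, depth_mean = cc$depth_mean,
    seq_error = cc$seq_error, n_f2 = cc$n_f2, qtl_spec = qtl_spec,
    polygenic_var = cc$polygenic_var, residual_var = cc$residual_var,
    batch_effects = unlist(cc$batch_effects), baseline = cc$baseline,
    seed = cfg$seed)
}

#' Run the full simulate -> genotype -> phenotype -> map pipeline
#'
#' Executes the enabled stages in dependency order, writes every
#' intermediate file under `out_dir` with stable names, and returns (and
#' writes) a run report with per-stage row counts, QC exclusions,
#' thresholds, significant loci and the seed chain. A stage failure
#' aborts with the stage named; files already written are retained.
#'
#' @param config a `run_config` (or anything [run_config()] accepts).
#' @param out_dir output directory (created if needed).
#' @return the run report (list), invisibly written as YAML and text.
#' @export
run_pipeline <- function(config = NULL, out_dir) {
  cfg <- run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config_resolved.yaml"))
  report <- list(seed = cfg$seed,
                 seed_chain = list(panel = cfg$seed,
                                   cohort = cfg$seed + 1000L,
                                   phenotypes = cfg$seed + 2000L,
                                   permutations = cfg$seed + 3000L))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  ccfg <- cross_config_from(cfg)

  sim <- NULL; traits_df <- NULL
  if (isTRUE(cfg$stages$simulate)) {
    simres <- stage("simulate", {
      s <- simulate_f2_cohort(ccfg)
      write_panel_tsv(s$panel, file.path(out_dir, "panel.tsv"))
      write_panel_vcf(s$panel, ccfg$layout, file.path(out_dir, "panel.vcf"))
      write_counts_tsv(s$counts, file.path(out_dir, "allele_counts.tsv"))
      tr <- simulate_phenotypes(s$truth, ccfg)
      write_traits_tsv(tr, file.path(out_dir, "traits_raw.tsv"))
      truth_bed(s$truth, file.path(out_dir, "true_blocks.bed"))
      list(sim = s, traits = tr)
    })
    sim <- simres$sim
    traits_df <- simres$traits
    report$simulate <- list(n_f2 = ccfg$n_f2, n_snps = nrow(sim$panel),
                            n_bins = nrow(sim$truth$bins),
                            pve_realized = attr(traits_df, "pve_realized"))
  }

  calls <- NULL; pseudo <- NULL; freqs <- NULL
  if (isTRUE(cfg$stages$genotype)) {
    if (is.null(sim)) stop("pipeline stage 'genotype' failed: no simulated inputs")
    res <- stage("genotype", {
      fr <- bin_allele_counts(sim$counts, sim$panel, ccfg$layout)
      qc <- qc_samples(fr, cfg$qc$min_informative)
      keep <- match(qc$kept, fr$samples)
      fr_kept <- subset_bin_freq(fr, keep)
      spec <- hmm_spec(variance = cfg$hmm$emission_var,
                       trans_prob = cfg$hmm$trans_prob)
      cl <- fill_missing(decode_genotypes(fr_kept, spec))
      write_blocks_bed(cl, file.path(out_dir, "called_blocks.bed"))
      ps <- build_pseudosnps(cl)
      write_pseudosnps_tsv(ps, file.path(out_dir, "pseudosnps.tsv"))
      list(freqs = fr, qc = qc, calls = cl, pseudo = ps)
    })
    freqs <- res$freqs; calls <- res$calls; pseudo <- res$pseudo
    report$genotype <- list(
      n_kept = length(res$qc$kept), n_excluded = length(res$qc$excluded),
      excluded = res$qc$excluded,
      n_calls = length(calls$states),
      state_changes_q90 = unname(stats::quantile(count_state_changes(calls),
                                                 0.9, type = 1)))
  }

  y <- NULL
  if (isTRUE(cfg$stages$traits)) {
    if (is.null(traits_df) || is.null(calls)) {
      stop("pipeline stage 'traits' failed: missing upstream outputs")
    }
    y <- stage("traits", {
      tr <- traits_df[match(calls$samples, traits_df$sample), , drop = FALSE]
      v <- switch(cfg$traits$normalization,
        invnorm = inverse_normalize(tr$y, tr$batch),
        equate = equate_batch_means(tr$y, tr$batch,
                                    cfg$traits$reference_batch),
        none = tr$y)
      out <- data.frame(sample = tr$sample, batch = tr$batch,
                        y_raw = tr$y, y = v, stringsAsFactors = FALSE)
      write_traits_tsv(out, file.path(out_dir, "traits_normalized.tsv"))
      out
    })
    report$traits <- list(normalization = cfg$traits$normalization,
                          n = nrow(y))
  }

  qtl_res <- NULL
  if (isTRUE(cfg$stages$qtl)) {
    if (is.null(pseudo) || is.null(y)) {
      stop("pipeline stage 'qtl' failed: missing upstream outputs")
    }
    qtl_res <- stage("qtl", {
      ctx <- scan_context(pseudo)
      sc <- scan_with_context(y$y, ctx)
      perm <- permutation_threshold(y$y, pseudo, n_perm = cfg$qtl$n_perm,
                                    seed = cfg$seed + 3000L, ctx = ctx)
      bonf <- bonferroni_threshold(ncol(pseudo$dosage), cfg$qtl$alpha)
      sig <- call_significant(sc, perm$threshold, bonf)
      write_scan_tsv(sig$scan, file.path(out_dir, "association.tsv"))
      data.table::fwrite(sig$loci, file.path(out_dir, "loci.tsv"), sep = "\t")
      yaml::write_yaml(list(permutation = perm$threshold,
                            per_perm_min = as.list(perm$per_perm_min),
                            bonferroni = bonf),
                       file.path(out_dir, "thresholds.yaml"))
      list(scan = sig$scan, loci = sig$loci, perm = perm, bonf = bonf)
    })
    report$qtl <- list(n_pseudosnps = ncol(pseudo$dosage),
                       perm_threshold = qtl_res$perm$threshold,
                       bonferroni_threshold = qtl_res$bonf,
                       n_loci = nrow(qtl_res$loci),
                       loci = if (nrow(qtl_res$loci)) qtl_res$loci else NULL)
  }

  if (isTRUE(cfg$stages$evaluate) && !is.null(sim) && !is.null(calls)) {
    report$evaluate <- stage("evaluate", {
      compare_to_truth(calls, sim$truth,
                       loci = if (!is.null(qtl_res)) qtl_res$loci else NULL,
                       qtl_spec = ccfg$qtl_spec,
                       hit_dist_bp = cfg$qtl$qtl_hit_bp)
    })
  }

  yaml::write_yaml(report_serializable(report),
                   file.path(out_dir, "report.yaml"))
  writeLines(format_report(report), file.path(out_dir, "report.txt"))
  invisible(report)
}

#' Subset a cohort frequency series to selected samples
#'
#' @param freqs a `bin_freq`.
#' @param idx row indices (or sample names) to keep.
#' @return the subsetted `bin_freq`.
#' @export
subset_bin_freq <- function(freqs, idx) {
  if (is.character(idx)) idx <- match(idx, freqs$samples)
  freqs$f <- freqs$f[idx, , drop = FALSE]
  freqs$reads <- freqs$reads[idx, , drop = FALSE]
  freqs$samples <- freqs$samples[idx]
  freqs
}

#' Write true simulated genotype blocks as BED
#'
#' @param truth an `f2_truth`.
#' @param path output file.
#' @export
truth_bed <- function(truth, path) {
  calls_like <- structure(list(states = truth$states,
                               filled = matrix(FALSE, nrow(truth$states),
                                               ncol(truth$states)),
                               bins = truth$bins,
                               samples = rownames(truth$states),
                               layout = truth$layout),
                          class = "geno_calls")
  write_blocks_bed(calls_like, path)
}

#' Evaluate a run against simulated ground truth
#'
#' @param calls filled `geno_calls` for the analyzed samples.
#' @param truth the `f2_truth` they were simulated from.
#' @param loci optional significant-locus table from [call_significant()].
#' @param qtl_spec optional true QTL table (`chrom`, `bin`).
#' @param hit_dist_bp maximum peak-to-truth distance counted as a hit.
#' @return list with genotype accuracy, breakpoint localization error
#'   (bp), called/true breakpoint counts, and per-QTL detection results.
#' @export
compare_to_truth <- function(calls, truth, loci = NULL, qtl_spec = NULL,
                             hit_dist_bp = 5e5) {
  stopifnot(inherits(calls, "geno_calls"), inherits(truth, "f2_truth"))
  if (!identical(calls$bins$id, truth$bins$id)) {
    stop("run and truth use different bin layouts")
  }
  idx <- match(calls$samples, rownames(truth$states))
  if (anyNA(idx)) stop("called samples absent from truth")
  ts <- truth$states[idx, , drop = FALSE]
  accuracy <- mean(calls$states == ts)

  bins <- calls$bins
  errs <- c(); n_called <- 0; n_true <- 0
  for (i in seq_along(calls$samples)) {
    gam <- truth$gametes[[idx[i]]]
    for (cn in unique(bins$chrom)) {
      bi <- which(bins$chrom == cn)
      st <- calls$states[i, bi]
      chg <- which(diff(st) != 0)
      called_pos <- bins$start[bi][chg + 1]
      true_pos <- sort(c(gam[[cn]]$mat$breaks, gam[[cn]]$pat$breaks))
      n_called <- n_called + length(called_pos)
      n_true <- n_true + length(true_pos)
      if (length(called_pos) && length(true_pos)) {
        errs <- c(errs, vapply(called_pos,
                               function(p) min(abs(p - true_pos)), 0))
      }
    }
  }
  out <- list(genotype_accuracy = accuracy,
              breakpoint_error_bp = if (length(errs)) mean(errs) else NA_real_,
              n_breakpoints_called = n_called,
              n_breakpoints_true = n_true)
  if (!is.null(qtl_spec) && nrow(qtl_spec)) {
    hits <- lapply(seq_len(nrow(qtl_spec)), function(j) {
      true_start <- qtl_spec$bin[j] * calls$layout$bin_size
      d <- if (!is.null(loci) && nrow(loci)) {
        same <- loci$chrom == qtl_spec$chrom[j]
        if (any(same)) min(abs(loci$peak_start[same] - true_start)) else Inf
      } else Inf
      data.frame(chrom = qtl_spec$chrom[j], bin = qtl_spec$bin[j],
                 peak_distance_bp = d, detected = is.finite(d) & d <= hit_dist_bp)
    })
    out$qtl <- do.call(rbind, hits)
  }
  out
}

report_serializable <- function(report) {
  rapply(report, function(x) {
    if (is.data.frame(x)) lapply(x, as.vector) else x
  }, how = "replace")
}

format_report <- function(report) {
  unlist(lapply(names(report), function(nm) {
    val <- report[[nm]]
    if (is.data.frame(val)) {
      c(paste0(nm, ":"), utils::capture.output(print(val)))
    } else if (is.list(val)) {
      c(paste0(nm, ":"),
        paste0("  ", names(val), ": ",
               vapply(val, function(v) paste(format(unlist(v)), collapse = " "),
                      "")))
    } else paste0(nm, ": ", paste(format(val), collapse = " "))
  }))
}
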