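#' @importFrom data.table fread fwrite
NULL

#' Write the SNP panel as TSV
#'
#' Columns: chrom, pos (0-based), cab_allele, kaga_allele.
#' @param panel a `snp_panel`.
#' @param path output file.
#' @export
write_panel_tsv <- function(panel, path) {
  data.table::fwrite(as.data.frame(panel), path, sep = "\t")
  invisible(path)
}

#' Write the SNP panel as a minimal VCF
#'
#' Biallelic records with REF = Cab allele, ALT = Kaga allele and the two
#' parental samples genotyped 0/0 (Cab) and 1/1 (Kaga). Positions are
#' converted to the 1-based VCF convention.
#'
#' @param panel a `snp_panel`.
#' @param layout the `genome_layout` (for contig headers).
#' @param path output file.
#' @export
write_panel_vcf <- function(panel, layout, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=f2qtl",
    sprintf("##contig=<ID=%s,length=%d>", layout$chrom$chrom,
            as.integer(layout$chrom$length)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tCab\tKaga"
  ), con)
  writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t0/0\t1/1",
                     panel$chrom, panel$pos + 1L,
                     panel$cab_allele, panel$kaga_allele), con)
  invisible(path)
}

#' Read a SNP panel from TSV or minimal VCF
#'
#' TSV must carry chrom/pos/cab_allele/kaga_allele; VCF (detected by
#' extension or header) is read taking REF as the Cab-type allele and ALT
#' as the Kaga-type allele, converting positions to 0-based.
#'
#' @param path input file.
#' @return a `snp_panel` data.frame.
#' @export
read_panel <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("^##fileformat=VCF", first)) {
    tab <- data.table::fread(path, skip = "#CHROM", header = TRUE,
                             data.table = FALSE)
    panel <- data.frame(chrom = tab[["#CHROM"]], pos = tab$POS - 1L,
                        cab_allele = tab$REF, kaga_allele = tab$ALT,
                        stringsAsFactors = FALSE)
  } else {
    panel <- data.table::fread(path, data.table = FALSE)
    stopifnot(all(c("chrom", "pos", "cab_allele", "kaga_allele") %in% names(panel)))
  }
  class(panel) <- c("snp_panel", "data.frame")
  panel
}

#' Write per-sample allele read counts as long-format TSV
#'
#' Columns: sample, chrom, pos, cab_reads, kaga_reads. Sites with zero
#' total reads are kept (the binning step needs the panel anyway).
#'
#' @param counts an `allele_counts`.
#' @param path output file.
#' @param drop_zero omit zero-coverage site rows (default TRUE; shrinks
#'   ~1x data substantially).
#' @export
write_counts_tsv <- function(counts, path, drop_zero = TRUE) {
  n <- length(counts$samples)
  S <- nrow(counts$sites)
  long <- data.frame(
    sample = rep(counts$samples, each = S),
    chrom = rep(counts$sites$chrom, n),
    pos = rep(counts$sites$pos, n),
    cab_reads = as.vector(t(counts$cab)),
    kaga_reads = as.vector(t(counts$kaga)),
    stringsAsFactors = FALSE
  )
  if (drop_zero) long <- long[long$cab_reads + long$kaga_reads > 0, ]
  data.table::fwrite(long, path, sep = "\t")
  invisible(path)
}

#' Read allele counts from long-format TSV
#'
#' @param path input file.
#' @param panel the `snp_panel` (defines the full site set; absent
#'   sample/site rows become zero counts).
#' @param samples optional sample ordering.
#' @return an `allele_counts`.
#' @export
read_counts_tsv <- function(path, panel, samples = NULL) {
  long <- data.table::fread(path, data.table = FALSE)
  if (is.null(samples)) samples <- sort(unique(long$sample))
  key <- paste(panel$chrom, panel$pos)
  si <- match(paste(long$chrom, long$pos), key)
  if (anyNA(si)) stop("counts file contains sites absent from the panel")
  ri <- match(long$sample, samples)
  cab <- matrix(0L, length(samples), nrow(panel),
                dimnames = list(samples, NULL))
  kaga <- cab
  cab[cbind(ri, si)] <- long$cab_reads
  kaga[cbind(ri, si)] <- long$kaga_reads
  structure(list(cab = cab, kaga = kaga, sites = panel, samples = samples),
            class = "allele_counts")
}

#' Write recombination blocks as BED
#'
#' Collapses consecutive same-state bins per sample and chromosome into
#' blocks: chrom, start, end, state, sample, any_filled.
#'
#' @param calls a filled `geno_calls`.
#' @param path output file.
#' @export
write_blocks_bed <- function(calls, path) {
  bins <- calls$bins
  rows <- list()
  for (i in seq_along(calls$samples)) {
    for (cn in unique(bins$chrom)) {
      bi <- which(bins$chrom == cn)
      st <- calls$states[i, bi]
      fl <- calls$filled[i, bi]
      r <- rle(st)
      e <- cumsum(r$lengths)
      s <- e - r$lengths + 1
      rows[[length(rows) + 1]] <- data.frame(
        chrom = cn, start = bins$start[bi][s], end = bins$end[bi][e],
        state = r$values, sample = calls$samples[i],
        any_filled = vapply(seq_along(s),
                            function(j) any(fl[s[j]:e[j]]), TRUE),
        stringsAsFactors = FALSE)
    }
  }
  data.table::fwrite(do.call(rbind, rows), path, sep = "\t")
  invisible(path)
}

#' Write the pseudo-SNP dosage matrix as TSV
#'
#' First column `sample`, then one column per bin id.
#' @param pseudo a `pseudo_snps`.
#' @param path output file.
#' @export
write_pseudosnps_tsv <- function(pseudo, path) {
  df <- data.frame(sample = rownames(pseudo$dosage), pseudo$dosage,
                   check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Write / read a trait table as TSV
#' @param traits a data.frame with a `sample` column.
#' @param path file path.
#' @export
write_traits_tsv <- function(traits, path) {
  data.table::fwrite(as.data.frame(traits), path, sep = "\t")
  invisible(path)
}

#' @rdname write_traits_tsv
#' @export
read_traits_tsv <- function(path) {
  out <- data.table::fread(path, data.table = FALSE)
  class(out) <- c("trait_table", "data.frame")
  out
}

#' Write / read an oscillation trace as CSV (time_min, intensity)
#' @param trace an `osc_trace`.
#' @param path file path.
#' @export
write_trace_csv <- function(trace, path) {
  data.table::fwrite(as.data.frame(trace)[, c("time_min", "intensity")], path)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  out <- data.table::fread(path, data.table = FALSE)
  stopifnot(all(c("time_min", "intensity") %in% names(out)))
  attr(out, "interval") <- stats::median(diff(out$time_min))
  class(out) <- c("osc_trace", "data.frame")
  out
}

#' Write an association scan as TSV (Manhattan-ready)
#' @param scan a `qtl_scan` (optionally with significance flags).
#' @param path file path.
#' @export
write_scan_tsv <- function(scan, path) {
  data.table::fwrite(as.data.frame(scan), path, sep = "\t")
  invisible(path)
}
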