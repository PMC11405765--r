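#' Rank-based inverse normal transformation within batches
#'
#' Within each batch j of size N_j (non-missing values), transforms each
#' value to z = qnorm(rank / (N_j + 0.5)) with ascending average ranks for
#' ties. Removes between-batch location/scale differences entirely (only
#' within-batch ranks survive), which is how batch-confounded microscope
#' effects are neutralized before association testing. Missing values
#' propagate as missing.
#'
#' @param values numeric vector.
#' @param batch_labels batch label per value (single batch if NULL).
#' @return numeric vector of z-scores.
#' @export
inverse_normalize <- function(values, batch_labels = NULL) {
  if (length(values) == 0) stop("empty input")
  if (is.null(batch_labels)) batch_labels <- rep("all", length(values))
  if (length(batch_labels) != length(values)) stop("batch labels length mismatch")
  z <- rep(NA_real_, length(values))
  for (b in unique(batch_labels)) {
    i <- which(batch_labels == b & !is.na(values))
    if (!length(i)) next
    r <- rank(values[i], ties.method = "average")
    z[i] <- stats::qnorm(r / (length(i) + 0.5))
  }
  z
}

#' Equate batch means to a reference batch
#'
#' Shifts every non-reference batch additively so that its mean equals
#' the reference batch's mean; the reference batch is unchanged. This is
#' the alternative, scale-preserving batch correction (the trait keeps
#' its original units).
#'
#' @param values numeric vector.
#' @param batch_labels batch label per value.
#' @param reference_batch label of the reference batch.
#' @return adjusted numeric vector.
#' @export
equate_batch_means <- function(values, batch_labels, reference_batch) {
  if (length(values) != length(batch_labels)) stop("batch labels length mismatch")
  if (!reference_batch %in% batch_labels) stop("unknown reference batch")
  ref_mean <- mean(values[batch_labels == reference_batch], na.rm = TRUE)
  out <- values
  for (b in setdiff(unique(batch_labels), reference_batch)) {
    i <- batch_labels == b
    out[i] <- values[i] + (ref_mean - mean(values[i], na.rm = TRUE))
  }
  out
}

#' Egg volume under the oblate-spheroid approximation
#'
#' V = 4/3 * pi * b^2 * c with b the semi-major and c the semi-minor axis.
#'
#' @param semi_major_b semi-major axis (>= 0).
#' @param semi_minor_c semi-minor axis (>= 0).
#' @return volume in cubic input units.
#' @export
egg_volume <- function(semi_major_b, semi_minor_c) {
  if (any(semi_major_b < 0) || any(semi_minor_c < 0)) {
    stop("axes must be non-negative")
  }
  4 / 3 * pi * semi_major_b^2 * semi_minor_c
}

#' Assemble the per-sample trait table from component measurements
#'
#' Full-joins period summaries, size measurements and the batch map on the
#' sample id without dropping any sample; missing cells stay NA and the
#' join audit (ids absent from each input) is attached.
#'
#' @param periods data.frame `sample`, `period_mean`, `period_intercept`.
#' @param sizes data.frame `sample` plus size columns (e.g.
#'   `psm_area_um2`, `somite_area_um2`); NULL to skip.
#' @param batch_map data.frame `sample`, `batch`; NULL to skip.
#' @return data.frame of class `trait_table` with attribute `join_audit`.
#' @export
assemble_trait_table <- function(periods, sizes = NULL, batch_map = NULL) {
  pieces <- Filter(Negate(is.null), list(periods = periods, sizes = sizes,
                                         batch_map = batch_map))
  for (nm in names(pieces)) {
    p <- pieces[[nm]]
    if (!"sample" %in% names(p)) stop(nm, " lacks a 'sample' column")
    if (anyDuplicated(p$sample)) stop("duplicate sample ids in ", nm)
  }
  all_ids <- unique(unlist(lapply(pieces, `[[`, "sample")))
  out <- data.frame(sample = all_ids, stringsAsFactors = FALSE)
  audit <- list()
  for (nm in names(pieces)) {
    p <- pieces[[nm]]
    out <- merge(out, p, by = "sample", all.x = TRUE, sort = FALSE)
    audit[[nm]] <- setdiff(all_ids, p$sample)
  }
  out <- out[match(all_ids, out$sample), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "join_audit") <- audit
  class(out) <- c("trait_table", "data.frame")
  out
}
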