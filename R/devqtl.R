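#' Genetic relationship matrix from pseudo-SNP dosages
#'
#' Standardized (GCTA-style) GRM: G_jk = (1/M) * sum_i (x_ij - 2 p_i)
#' (x_ik - 2 p_i) / (2 p_i (1 - p_i)) over polymorphic markers i, with
#' allele frequency p_i estimated from the analyzed sample. Monomorphic
#' markers are excluded and counted.
#'
#' @param dosages a `pseudo_snps` object or samples x markers matrix with
#'   entries in \{0, 1, 2\}.
#' @param exclude_chrom optional chromosome name to leave out (requires a
#'   `pseudo_snps` object carrying bin coordinates).
#' @return object of class `grm`: matrix `G`, marker count `M`,
#'   `n_monomorphic`, `excluded_chrom`.
#' @export
compute_grm <- function(dosages, exclude_chrom = NULL) {
  if (inherits(dosages, "pseudo_snps")) {
    X <- dosages$dosage
    chroms <- dosages$bins$chrom
  } else {
    X <- as.matrix(dosages)
    chroms <- NULL
  }
  if (nrow(X) < 2) stop("need at least 2 samples")
  if (!is.null(exclude_chrom)) {
    if (is.null(chroms)) stop("chromosome info required for LOCO")
    keep <- chroms != exclude_chrom
    if (!any(!keep)) stop("excluded chromosome '", exclude_chrom, "' has no markers")
    X <- X[, keep, drop = FALSE]
  }
  p <- colMeans(X) / 2
  # polymorphic = segregating AND varying (an all-heterozygous column has
  # p = 0.5 but carries no relatedness information)
  v <- colMeans(X^2) - colMeans(X)^2
  poly <- p > 0 & p < 1 & v > 0
  if (!any(poly)) stop("all markers are monomorphic")
  Xp <- X[, poly, drop = FALSE]
  pp <- p[poly]
  Z <- sweep(Xp, 2, 2 * pp)
  Z <- sweep(Z, 2, sqrt(2 * pp * (1 - pp)), "/")
  M <- ncol(Z)
  structure(list(G = tcrossprod(Z) / M, M = M,
                 n_monomorphic = sum(!poly),
                 excluded_chrom = exclude_chrom),
            class = "grm")
}

#' Leave-one-chromosome-out GRM
#'
#' GRM computed from all markers NOT on the named chromosome, so that a
#' tested marker's own chromosome never contributes to the random-effect
#' covariance (avoiding proximal contamination).
#'
#' @param dosages a `pseudo_snps` object.
#' @param chromosome chromosome to exclude.
#' @return a `grm`.
#' @export
loco_grm <- function(dosages, chromosome) {
  stopifnot(inherits(dosages, "pseudo_snps"))
  if (length(unique(dosages$bins$chrom)) < 2) {
    stop("LOCO requires at least 2 chromosomes")
  }
  compute_grm(dosages, exclude_chrom = chromosome)
}

#' Restricted maximum likelihood fit of the null mixed model
#'
#' Fits y = W alpha + g + e with g ~ N(0, sigma_g^2 G), e ~ N(0,
#' sigma_e^2 I) by eigendecomposition of G and one-dimensional
#' optimization of the restricted log-likelihood over the variance ratio
#' lambda = sigma_g^2 / sigma_e^2 (coarse grid then golden-section
#' refinement, so a boundary optimum at lambda ~ 0 is found reliably).
#'
#' @param y phenotype vector (no missing values).
#' @param grm a `grm` (or bare symmetric matrix).
#' @param covariates matrix of fixed covariates (intercept added
#'   automatically; NULL for intercept only).
#' @return list of class `lmm_fit`: `sigma_g`, `sigma_e`, `lambda`, `h2`,
#'   `loglik`, plus the eigendecomposition (`eigval`, `eigvec`) for reuse.
#' @export
fit_null_lmm <- function(y, grm, covariates = NULL) {
  G <- if (inherits(grm, "grm")) grm$G else as.matrix(grm)
  n <- length(y)
  if (nrow(G) != n) stop("phenotype length does not match GRM dimension")
  if (anyNA(y)) stop("missing phenotype values; drop them beforehand")
  W <- cbind(intercept = rep(1, n), covariates)
  eg <- eigen(G, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- crossprod(U, y)
  Wt <- crossprod(U, W)
  fit <- reml_profile(yt, Wt, d, W)
  structure(c(fit, list(eigval = d, eigvec = U, W = W, mean_diag = mean(diag(G)))),
            class = "lmm_fit")
}

# Restricted log-likelihood profiled over lambda, on rotated data.
reml_loglik <- function(log_lambda, yt, Wt, d, logdet_WW) {
  lam <- exp(log_lambda)
  D <- lam * d + 1
  w <- 1 / D
  q <- ncol(Wt)
  WtW <- crossprod(Wt, Wt * w)
  alpha <- solve(WtW, crossprod(Wt, yt * w))
  r <- yt - Wt %*% alpha
  rss <- sum(w * r^2)
  nq <- length(yt) - q
  sigma_e <- rss / nq
  -0.5 * (nq * log(2 * pi * sigma_e) + nq + sum(log(D)) +
            determinant(WtW)$modulus[1] - logdet_WW)
}

reml_profile <- function(yt, Wt, d, W) {
  logdet_WW <- determinant(crossprod(W))$modulus[1]
  grid <- seq(-12, 8, length.out = 41)
  ll <- vapply(grid, reml_loglik, 0, yt = yt, Wt = Wt, d = d,
               logdet_WW = logdet_WW)
  i <- which.max(ll)
  lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
  opt <- stats::optimize(reml_loglik, c(lo, hi), maximum = TRUE,
                         yt = yt, Wt = Wt, d = d, logdet_WW = logdet_WW,
                         tol = 1e-8)
  lam <- exp(opt$maximum)
  if (opt$objective < ll[i]) lam <- exp(grid[i])
  D <- lam * d + 1
  w <- 1 / D
  WtW <- crossprod(Wt, Wt * w)
  alpha <- solve(WtW, crossprod(Wt, yt * w))
  rss <- sum(w * (yt - Wt %*% alpha)^2)
  sigma_e <- rss / (length(yt) - ncol(Wt))
  sigma_g <- lam * sigma_e
  md <- mean(d)
  list(lambda = lam, sigma_g = sigma_g, sigma_e = sigma_e,
       h2 = sigma_g * md / (sigma_g * md + sigma_e),
       loglik = max(opt$objective, ll[i]), alpha = as.vector(alpha))
}

#' Leave-one-chromosome-out mixed-model association scan
#'
#' For every pseudo-SNP, tests its additive fixed effect added to the
#' null mixed model whose GRM excludes that marker's chromosome. Variance
#' components are fitted once per excluded chromosome and reused across
#' that chromosome's markers. Per marker, a generalized least-squares
#' regression in the rotated space gives the effect and its Wald
#' chi-square (1 df) p-value, with the residual scale re-estimated from
#' the weighted residual sum of squares (df = n - q - 1). Monomorphic
#' markers get p = 1 and a flag.
#'
#' @param y phenotype vector aligned with dosage rows.
#' @param dosages a `pseudo_snps`.
#' @param covariates optional fixed-covariate matrix.
#' @param lambda_override force the variance ratio (0 collapses the model
#'   to ordinary least squares); NULL (default) uses the REML fit.
#' @return data.frame of class `qtl_scan`: `chrom`, `start`, `end`, `id`,
#'   `beta`, `se`, `chisq`, `p`, `monomorphic`; attribute `null_fits`.
#' @export
association_scan <- function(y, dosages, covariates = NULL,
                             lambda_override = NULL) {
  stopifnot(inherits(dosages, "pseudo_snps"))
  ctx <- scan_context(dosages, covariates)
  scan_with_context(y, ctx, lambda_override = lambda_override)
}

# Precompute everything phenotype-independent: per-chromosome LOCO GRM
# eigendecompositions and rotated covariates/dosages. Permutations and
# repeated scans reuse this.
#' @rdname association_scan
#' @export
scan_context <- function(dosages, covariates = NULL) {
  stopifnot(inherits(dosages, "pseudo_snps"))
  X <- dosages$dosage
  n <- nrow(X)
  W <- cbind(intercept = rep(1, n), covariates)
  chroms <- unique(dosages$bins$chrom)
  if (length(chroms) < 2) stop("LOCO scan requires at least 2 chromosomes")
  per <- lapply(chroms, function(cn) {
    g <- loco_grm(dosages, cn)
    eg <- eigen(g$G, symmetric = TRUE)
    d <- pmax(eg$values, 0)
    U <- eg$vectors
    cols <- which(dosages$bins$chrom == cn)
    Xc <- X[, cols, drop = FALSE]
    mono <- apply(Xc, 2, function(v) all(v == v[1]))
    list(chrom = cn, cols = cols, d = d, U = U,
         Wt = crossprod(U, W), Xt = crossprod(U, Xc), mono = mono)
  })
  names(per) <- chroms
  list(per = per, W = W, bins = dosages$bins, n = n)
}

#' @rdname association_scan
#' @param ctx a context from scan_context().
#' @export
scan_with_context <- function(y, ctx, lambda_override = NULL) {
  if (length(y) != ctx$n) stop("phenotype length mismatch")
  if (anyNA(y)) stop("missing phenotype values; drop them beforehand")
  out <- vector("list", length(ctx$per))
  null_fits <- list()
  logdet_WW <- determinant(crossprod(ctx$W))$modulus[1]
  for (k in seq_along(ctx$per)) {
    pc <- ctx$per[[k]]
    yt <- crossprod(pc$U, y)
    if (is.null(lambda_override)) {
      fit <- reml_profile(yt, pc$Wt, pc$d, ctx$W)
      lam <- fit$lambda
    } else {
      lam <- lambda_override
      fit <- list(lambda = lam)
    }
    null_fits[[pc$chrom]] <- fit
    w <- 1 / (lam * pc$d + 1)
    sw <- sqrt(w)
    ys <- sw * yt
    Ws <- sw * pc$Wt
    qr_W <- qr(Ws)
    yr <- stats::resid(stats::lm.fit(Ws, ys))
    Xr <- sw * pc$Xt
    Xr <- Xr - Ws %*% qr.coef(qr_W, Xr)
    sxx <- colSums(Xr^2)
    sxy <- colSums(Xr * yr)
    syy <- sum(yr^2)
    q <- ncol(ctx$W)
    dfree <- ctx$n - q - 1
    beta <- ifelse(sxx > 1e-12, sxy / sxx, NA_real_)
    rss <- pmax(syy - ifelse(sxx > 1e-12, sxy^2 / sxx, 0), 0)
    sigma2 <- rss / dfree
    se <- sqrt(sigma2 / pmax(sxx, 1e-12))
    chisq <- ifelse(sxx > 1e-12, beta^2 / se^2, 0)
    p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
    mono <- pc$mono | sxx <= 1e-12
    p[mono] <- 1
    chisq[mono] <- 0
    bb <- ctx$bins[pc$cols, , drop = FALSE]
    out[[k]] <- data.frame(chrom = bb$chrom, start = bb$start, end = bb$end,
                           id = bb$id, beta = beta, se = se, chisq = chisq,
                           p = p, monomorphic = mono,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[match(ctx$bins$id, res$id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "null_fits") <- null_fits
  class(res) <- c("qtl_scan", "data.frame")
  res
}

#' Permutation genome-wide significance threshold
#'
#' Permutes the rows of (phenotype, covariates) jointly against the
#' genotypes with `n_perm` distinct seeds, runs a full LOCO scan per
#' permutation, and returns the single lowest p-value observed across all
#' permutations and markers as the significance threshold, together with
#' the per-permutation minima.
#'
#' @param y phenotype vector.
#' @param dosages a `pseudo_snps`.
#' @param covariates optional covariate matrix (permuted with y).
#' @param n_perm number of permutations (default 10).
#' @param seed base seed; permutation k uses seed + k.
#' @param ctx optional precomputed [scan_context()] (only valid without
#'   covariates, since covariates are permuted).
#' @return list `threshold`, `per_perm_min`, `n_perm`, `seeds`.
#' @export
permutation_threshold <- function(y, dosages, covariates = NULL,
                                  n_perm = 10, seed = 1, ctx = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  seeds <- seed + seq_len(n_perm)
  if (anyDuplicated(seeds)) stop("seeds must be distinct")
  mins <- vapply(seeds, function(s) {
    set.seed(s)
    perm <- sample.int(length(y))
    if (is.null(covariates)) {
      context <- if (is.null(ctx)) scan_context(dosages, NULL) else ctx
      sc <- scan_with_context(y[perm], context)
    } else {
      sc <- association_scan(y[perm], dosages,
                             covariates = covariates[perm, , drop = FALSE])
    }
    min(sc$p)
  }, 0)
  list(threshold = min(mins), per_perm_min = mins,
       n_perm = n_perm, seeds = seeds)
}

#' Bonferroni genome-wide threshold
#'
#' @param n_pseudosnps number of markers in the model (>= 1).
#' @param alpha family-wise error rate (default 0.05).
#' @return alpha / n.
#' @export
bonferroni_threshold <- function(n_pseudosnps, alpha = 0.05) {
  if (n_pseudosnps < 1) stop("n_pseudosnps must be >= 1")
  alpha / n_pseudosnps
}

#' Call significant loci from a scan and thresholds
#'
#' Flags markers below the permutation and Bonferroni thresholds and
#' merges runs of contiguous significant bins (same chromosome, adjacent
#' coordinates, significant under the permutation threshold) into loci,
#' each reported with its peak (minimum-p) bin.
#'
#' @param scan a `qtl_scan`.
#' @param perm_threshold permutation p-value threshold.
#' @param bonf_threshold Bonferroni p-value threshold.
#' @return list `scan` (with `sig_perm`, `sig_bonf` columns) and `loci`
#'   (data.frame `chrom`, `start`, `end`, `peak_id`, `peak_p`, `n_bins`,
#'   `sig_bonf`).
#' @export
call_significant <- function(scan, perm_threshold, bonf_threshold) {
  stopifnot(inherits(scan, "qtl_scan"))
  scan$sig_perm <- scan$p < perm_threshold
  scan$sig_bonf <- scan$p < bonf_threshold
  loci <- list()
  for (cn in unique(scan$chrom)) {
    sub <- scan[scan$chrom == cn, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    sig <- sub$sig_perm
    if (!any(sig)) next
    runs <- rle(sig)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    for (r in which(runs$values)) {
      blk <- sub[starts[r]:ends[r], , drop = FALSE]
      peak <- which.min(blk$p)
      loci[[length(loci) + 1]] <- data.frame(
        chrom = cn, start = min(blk$start), end = max(blk$end),
        peak_id = blk$id[peak], peak_start = blk$start[peak],
        peak_p = blk$p[peak], n_bins = nrow(blk),
        sig_bonf = any(blk$sig_bonf), stringsAsFactors = FALSE)
    }
  }
  loci <- if (length(loci)) do.call(rbind, loci) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               peak_id = character(), peak_start = numeric(),
               peak_p = numeric(), n_bins = integer(),
               sig_bonf = logical(), stringsAsFactors = FALSE)
  list(scan = scan, loci = loci)
}
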