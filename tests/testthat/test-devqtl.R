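# Small pseudo-SNP fixture with Mendelian dosages.
random_pseudo <- function(n, m, n_chrom = 2, seed = 1) {
  set.seed(seed)
  dos <- matrix(sample(0:2, n * m, replace = TRUE, prob = c(.25, .5, .25)),
                n, m)
  rownames(dos) <- sprintf("S%03d", seq_len(n))
  layout <- tiny_layout(n_chrom, m / n_chrom * 5000)
  bins <- bin_table(layout)
  colnames(dos) <- bins$id
  structure(list(dosage = dos, bins = bins,
                 monomorphic = apply(dos, 2, function(x) all(x == x[1])),
                 layout = layout),
            class = "pseudo_snps")
}

naive_grm <- function(X) {
  p <- colMeans(X) / 2
  keep <- p > 0 & p < 1
  X <- X[, keep, drop = FALSE]; p <- p[keep]
  n <- nrow(X); M <- ncol(X)
  G <- matrix(0, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    G[j, k] <- sum((X[j, ] - 2 * p) * (X[k, ] - 2 * p) /
                     (2 * p * (1 - p))) / M
  }
  G
}

test_that("GRM matches the naive double-loop oracle and its expectations", {
  set.seed(61)
  for (i in 1:5) {
    X <- matrix(sample(0:2, 20 * 200, replace = TRUE, prob = c(.25, .5, .25)),
                20, 200)
    g <- compute_grm(X)
    expect_lt(max(abs(g$G - naive_grm(X))), 1e-10)
  }

  # identical genotypes give identical relatedness entries
  X2 <- rbind(c(0, 1, 2, 1), c(0, 1, 2, 1), c(2, 1, 0, 1))
  g2 <- compute_grm(X2)
  expect_equal(g2$G[1, 2], g2$G[1, 1])
  expect_equal(g2$G[1, 2], g2$G[2, 2])

  # independent Mendelian dosages: off-diagonals ~0, diagonals ~1
  big <- random_pseudo(100, 5000, seed = 62)
  gb <- compute_grm(big)
  off <- gb$G[upper.tri(gb$G)]
  expect_lt(abs(mean(off)), 0.05)
  expect_lt(abs(mean(diag(gb$G)) - 1), 0.1)

  expect_error(compute_grm(matrix(1, 5, 4)), "monomorphic")
})

test_that("F2-cohort GRM has ~unit diagonal despite full-sib structure", {
  run <- genotyped_cohort()
  ps <- build_pseudosnps(run$calls)
  g <- compute_grm(ps)
  expect_lt(abs(mean(diag(g$G)) - 1), 0.1)
})

test_that("LOCO GRMs drop exactly one chromosome and converge to the full GRM", {
  ps <- random_pseudo(50, 1000, n_chrom = 5, seed = 63)
  g_loco <- loco_grm(ps, "chr2")
  expect_equal(g_loco$M + sum(ps$bins$chrom == "chr2") -
                 sum(ps$monomorphic[ps$bins$chrom == "chr2"]),
               compute_grm(ps)$M)
  expect_error(loco_grm(ps, "chrZ"), "no markers")
  one_chr <- random_pseudo(10, 20, n_chrom = 1, seed = 64)
  expect_error(loco_grm(one_chr, "chr1"), "at least 2")

  many <- random_pseudo(40, 2000, n_chrom = 20, seed = 65)
  g_full <- compute_grm(many)$G
  g_m <- loco_grm(many, "chr1")$G
  expect_lt(max(abs(g_m - g_full)), 0.1)
})

test_that("REML recovers variance components and sits at the optimum", {
  set.seed(66)
  n <- 500
  ps <- random_pseudo(n, 2000, n_chrom = 4, seed = 66)
  g <- compute_grm(ps)
  ev <- eigen(g$G, symmetric = TRUE)
  make_y <- function(h2) {
    d <- pmax(ev$values, 0)
    gg <- ev$vectors %*% (sqrt(d) * rnorm(n))
    gg <- gg / sd(gg) * sqrt(h2)
    as.vector(gg + rnorm(n, 0, sqrt(1 - h2)))
  }

  # heritability is weakly identified from one cohort, so parameter
  # recovery is asserted on averages over seeded replicates
  h0 <- replicate(8, fit_null_lmm(rnorm(n), g)$h2)
  expect_lt(mean(h0), 0.05)

  h5 <- replicate(8, fit_null_lmm(make_y(0.5), g)$h2)
  expect_lt(abs(mean(h5) - 0.5), 0.15)

  # restricted likelihood at the optimum beats 20 random variance ratios
  y5 <- make_y(0.5)
  fit5 <- fit_null_lmm(y5, g)
  U <- fit5$eigvec; d <- fit5$eigval
  yt <- crossprod(U, y5); Wt <- crossprod(U, fit5$W)
  ldWW <- determinant(crossprod(fit5$W))$modulus[1]
  for (ll in runif(20, -10, 6)) {
    expect_gte(fit5$loglik + 1e-6,
               f2qtl:::reml_loglik(ll, yt, Wt, d, ldWW))
  }
})

test_that("profiled restricted likelihood matches the direct matrix formula", {
  set.seed(77)
  n <- 60
  ps <- random_pseudo(n, 400, n_chrom = 2, seed = 77)
  G <- compute_grm(ps)$G
  y <- as.vector(chol(G + diag(n) * 1.5) %*% rnorm(n))
  W <- cbind(rep(1, n))
  # independent oracle: lR(lambda) from dense V = lambda*G + I
  direct <- function(lam) {
    V <- lam * G + diag(n)
    Vi <- solve(V)
    WVW <- t(W) %*% Vi %*% W
    P <- Vi - Vi %*% W %*% solve(WVW) %*% t(W) %*% Vi
    rss <- as.numeric(t(y) %*% P %*% y)
    nq <- n - ncol(W)
    s2 <- rss / nq
    -0.5 * (nq * log(2 * pi * s2) + nq + determinant(V)$modulus[1] +
              determinant(WVW)$modulus[1] - determinant(crossprod(W))$modulus[1])
  }
  eg <- eigen(G, symmetric = TRUE)
  yt <- crossprod(eg$vectors, y); Wt <- crossprod(eg$vectors, W)
  ldWW <- determinant(crossprod(W))$modulus[1]
  for (lam in c(0.1, 0.5, 1, 3)) {
    expect_equal(f2qtl:::reml_loglik(log(lam), yt, Wt, pmax(eg$values, 0), ldWW),
                 direct(lam), tolerance = 1e-8)
  }
})

test_that("with the genetic variance forced to zero the scan is exactly OLS", {
  set.seed(67)
  ps <- random_pseudo(120, 200, n_chrom = 2, seed = 67)
  y <- rnorm(120) + 0.4 * ps$dosage[, 17]
  sc <- association_scan(y, ps, lambda_override = 0)
  for (j in c(1, 17, 100)) {
    lmfit <- summary(lm(y ~ ps$dosage[, j]))
    tt <- coef(lmfit)[2, "t value"]
    p_ols <- pchisq(tt^2, df = 1, lower.tail = FALSE)
    expect_equal(sc$beta[j], coef(lmfit)[2, "Estimate"], tolerance = 1e-8)
    expect_equal(sc$p[j], p_ols, tolerance = 1e-8)
  }
})

test_that("a strong single QTL is localized and null p-values are uniform", {
  # PVE-0.2 QTL at n = 600, no polygenic background: the genome-wide
  # minimum p lands within 250 kb of the causal bin
  rep <- qtl_replicate_scan(seed = 68, n_f2 = 600, pve = 0.2)
  best <- rep$scan[which.min(rep$scan$p), ]
  expect_equal(best$chrom, "chr3")
  expect_lt(abs(best$start - 500 * 5000), 2.5e5)

  # with independent markers a pure-noise phenotype gives uniform p-values
  # (pseudo-SNPs from a cross are block-correlated, so their single-draw
  # empirical distribution would not estimate the marginal law)
  ps <- random_pseudo(200, 5000, n_chrom = 5, seed = 68)
  set.seed(680)
  sc_null <- association_scan(rnorm(200), ps)
  ks <- suppressWarnings(ks.test(sc_null$p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("monomorphic markers are flagged with p = 1, not an error", {
  ps <- random_pseudo(50, 100, seed = 69)
  ps$dosage[, 3] <- 1L
  ps$monomorphic[3] <- TRUE
  y <- rnorm(50)
  sc <- association_scan(y, ps)
  expect_equal(sc$p[3], 1)
  expect_true(sc$monomorphic[3])
})

test_that("identical row permutation of phenotype and genotypes changes nothing", {
  set.seed(70)
  ps <- random_pseudo(80, 300, seed = 70)
  y <- rnorm(80) + 0.5 * ps$dosage[, 7]
  sc <- association_scan(y, ps)
  perm <- sample.int(80)
  ps2 <- ps
  ps2$dosage <- ps$dosage[perm, , drop = FALSE]
  sc2 <- association_scan(y[perm], ps2)
  # invariance is exact in theory; eigendecomposition of the permuted GRM
  # introduces rounding at the optimizer tolerance
  expect_equal(sc2$p, sc$p, tolerance = 1e-6)
  expect_equal(sc2$beta, sc$beta, tolerance = 1e-6)
})

test_that("permutation threshold is the min over per-permutation minima", {
  set.seed(71)
  ps <- random_pseudo(60, 200, seed = 71)
  y <- rnorm(60)
  pt <- permutation_threshold(y, ps, n_perm = 5, seed = 123)
  expect_equal(pt$threshold, min(pt$per_perm_min))
  expect_length(pt$per_perm_min, 5)

  pt2 <- permutation_threshold(y, ps, n_perm = 5, seed = 123)
  expect_identical(pt$threshold, pt2$threshold)

  # more permutations can only lower (or keep) the threshold, seeds paired
  pt10 <- permutation_threshold(y, ps, n_perm = 10, seed = 123)
  expect_lte(pt10$threshold, pt$threshold)
  expect_equal(pt10$per_perm_min[1:5], pt$per_perm_min)

  expect_error(permutation_threshold(y, ps, n_perm = 0), "n_perm")
})

test_that("Bonferroni threshold is alpha over the marker count", {
  expect_equal(bonferroni_threshold(1000), 5e-5)
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_equal(bonferroni_threshold(100, alpha = 0.01), 1e-4)
  expect_error(bonferroni_threshold(0), "n_pseudosnps")
})

test_that("significant bins merge into loci with peak reporting", {
  ps <- random_pseudo(30, 20, n_chrom = 2, seed = 72)
  y <- rnorm(30)
  sc <- association_scan(y, ps)

  all1 <- sc; all1$p <- rep(1, nrow(sc))
  out <- call_significant(all1, 0.01, 0.001)
  expect_equal(nrow(out$loci), 0)

  one <- all1; one$p[5] <- 1e-6
  out1 <- call_significant(one, 0.01, 0.001)
  expect_equal(nrow(out1$loci), 1)
  expect_true(out1$loci$sig_bonf)
  expect_equal(out1$loci$peak_id, sc$id[5])

  adj <- all1; adj$p[5:6] <- c(1e-4, 5e-5)
  out2 <- call_significant(adj, 0.01, 1e-6)
  expect_equal(nrow(out2$loci), 1)
  expect_equal(out2$loci$n_bins, 2)
  expect_equal(out2$loci$peak_id, sc$id[6])
  expect_false(out2$loci$sig_bonf)
})
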