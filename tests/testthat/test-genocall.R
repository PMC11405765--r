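test_that("binned frequencies follow the read counts, 0.5 when empty", {
  layout <- tiny_layout(1, 15000)
  panel <- data.frame(chrom = "chr1", pos = c(100L, 200L, 5100L, 10100L),
                      cab_allele = "A", kaga_allele = "C",
                      stringsAsFactors = FALSE)
  class(panel) <- c("snp_panel", "data.frame")
  counts <- structure(list(
    cab = matrix(c(2L, 1L, 0L, 0L), 1),
    kaga = matrix(c(1L, 0L, 0L, 7L), 1),
    sites = panel, samples = "S01"), class = "allele_counts")
  fr <- bin_allele_counts(counts, panel, layout)
  expect_equal(as.vector(fr$f), c(1 / 4, 0.5, 1.0))  # 3:1 cab; empty; 0:7
  expect_equal(as.vector(fr$reads), c(4, 0, 7))
  expect_equal(fr$n_snps, c(2L, 1L, 1L))

  bad <- panel; bad$pos[1] <- 20000L
  counts_bad <- counts; counts_bad$sites <- bad
  expect_error(bin_allele_counts(counts_bad, bad, layout), "outside")
})

test_that("pure frequency runs decode to the matching homozygous states", {
  f0 <- make_freqs(rep(0, 100))
  expect_true(all(decode_genotypes(f0)$states == 0L))
  f2 <- make_freqs(rep(1, 100))
  expect_true(all(decode_genotypes(f2)$states == 2L))
  # short opposing runs: with the wide default emissions and near-zero
  # transitions, 3 bins of evidence per side cannot pay the switch cost, so
  # the optimum is the all-het compromise — exhaustive enumeration agrees
  f02 <- make_freqs(c(rep(0, 3), rep(1, 3)))
  st <- as.vector(decode_genotypes(f02)$states)
  expect_identical(st, enumerate_viterbi(c(rep(0, 3), rep(1, 3))))
  expect_identical(st, rep(1L, 6))
  # a sharper spec lets the same data split into hom blocks with one change
  sharp <- hmm_spec(variance = 0.05, trans_prob = 1e-2)
  st_sharp <- as.vector(decode_genotypes(f02, sharp)$states)
  expect_identical(st_sharp, enumerate_viterbi(c(rep(0, 3), rep(1, 3)), sharp))
  expect_identical(st_sharp, c(0L, 0L, 0L, 2L, 2L, 2L))
})

test_that("Viterbi matches exhaustive path enumeration on short chromosomes", {
  set.seed(71)
  spec <- hmm_spec()
  for (i in 1:40) {
    n <- sample(3:9, 1)
    f <- pmin(pmax(runif(n), 0), 1)
    fr <- make_freqs(f, layout = tiny_layout(1, n * 5000))
    got <- as.vector(decode_genotypes(fr, spec)$states)
    expect_identical(got, enumerate_viterbi(f, spec))
  }
})

test_that("missing bins are filled from the previous (else next) called bin", {
  calls <- make_calls(c(NA, 0L, NA, 2L))
  filled <- fill_missing(calls)
  expect_equal(as.vector(filled$states), c(0, 0, 0, 2))
  expect_equal(as.vector(filled$filled), c(TRUE, FALSE, TRUE, FALSE))

  lead <- fill_missing(make_calls(c(NA, NA, 1L)))
  expect_equal(as.vector(lead$states), c(1, 1, 1))

  intact <- make_calls(c(0L, 1L, 2L))
  expect_identical(fill_missing(intact)$states, intact$states)

  expect_error(fill_missing(make_calls(c(NA_integer_, NA_integer_))), "all bins missing")
})

test_that("coverage QC separates deep from shallow samples", {
  fr0 <- make_freqs(rep(0.5, 10), reads = matrix(0L, 1, 10))
  expect_equal(qc_samples(fr0, 0.5)$excluded, "S01")
  expect_length(qc_samples(fr0, 0.0)$excluded, 0)

  cfg_deep <- cross_config(layout = tiny_layout(1, 2.5e5), n_f2 = 5,
                           depth_mean = 1, seed = 81)
  cfg_thin <- cross_config(layout = tiny_layout(1, 2.5e5), n_f2 = 5,
                           depth_mean = 0.01, seed = 82)
  deep <- simulate_f2_cohort(cfg_deep)
  thin <- simulate_f2_cohort(cfg_thin)
  fr_deep <- bin_allele_counts(deep$counts, deep$panel, cfg_deep$layout)
  fr_thin <- bin_allele_counts(thin$counts, thin$panel, cfg_thin$layout)
  expect_length(qc_samples(fr_deep, 0.5)$excluded, 0)
  expect_length(qc_samples(fr_thin, 0.5)$kept, 0)
})

test_that("pseudo-SNP dosages mirror states and average ~1 under Mendel", {
  ps <- build_pseudosnps(make_calls(c(0L, 1L, 2L)))
  expect_equal(as.vector(ps$dosage), c(0, 1, 2))

  two <- build_pseudosnps(make_calls(rbind(c(0L, 1L), c(0L, 2L))))
  expect_equal(as.vector(two$monomorphic), c(TRUE, FALSE))

  run <- genotyped_cohort()
  ps <- build_pseudosnps(run$calls)
  col_means <- colMeans(ps$dosage)
  se <- sd(col_means) / sqrt(length(col_means))
  expect_lt(abs(mean(col_means) - 1), 0.05)
})

test_that("state-change counting is exact", {
  expect_equal(as.vector(count_state_changes(make_calls(c(0L, 0L, 0L, 0L)))), 0)
  expect_equal(as.vector(count_state_changes(make_calls(c(0L, 0L, 1L, 1L)))), 1)
  expect_equal(as.vector(count_state_changes(make_calls(c(0L, 1L, 0L, 1L)))), 3)
})

test_that("desk-scale genotyping is accurate and parsimonious", {
  run <- genotyped_cohort()
  acc <- mean(run$calls$states == run$sim$truth$states)
  expect_gte(acc, 0.95)

  # decoded changes never exceed true crossovers on the two gametes + 2
  changes <- count_state_changes(run$calls)
  for (i in seq_along(run$sim$truth$gametes)) {
    gam <- run$sim$truth$gametes[[i]]
    for (cn in names(gam)) {
      true_xo <- length(gam[[cn]]$mat$breaks) + length(gam[[cn]]$pat$breaks)
      expect_lte(changes[i, cn], true_xo + 2)
    }
  }
})

test_that("allele relabeling swaps homozygous states and keeps change counts", {
  set.seed(91)
  f <- runif(60)
  fr <- make_freqs(f, layout = tiny_layout(1, 3e5))
  fr_swapped <- make_freqs(1 - f, layout = tiny_layout(1, 3e5))
  a <- decode_genotypes(fr)
  b <- decode_genotypes(fr_swapped)
  expect_identical(as.vector(b$states), as.vector(2L - a$states))
  expect_identical(count_state_changes(fill_missing(a)),
                   count_state_changes(fill_missing(b)))
})
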