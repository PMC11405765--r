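test_that("panel sites are placed at the configured density, deterministically", {
  cfg <- cross_config(layout = tiny_layout(1, 5000), snp_density = 1 / 250,
                      seed = 5)
  counts <- vapply(1:1000, function(i) {
    cfg$seed <- i
    nrow(simulate_panel(cfg))
  }, 0)
  # expected 20 sites on one 5-kb bin, +- 3 SE of the Poisson mean
  se <- sqrt(20 / 1000)
  expect_lt(abs(mean(counts) - 20), 3 * se)

  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1, p2)
  expect_true(all(diff(p1$pos) > 0))
  expect_true(all(p1$cab_allele != p1$kaga_allele))

  expect_error(cross_config(snp_density = 0), "snp_density")
})

test_that("meiosis produces Poisson crossovers and consistent gametes", {
  expect_error(simulate_meiosis(5e6, -1), "crossover_mean")

  set.seed(11)
  g0 <- simulate_meiosis(5e6, 0)
  expect_length(g0$breaks, 0)
  expect_true(all(gamete_origin(g0, c(0, 2.5e6, 4.9e6)) == g0$start))

  set.seed(12)
  n_xo <- vapply(1:10000, function(i) length(simulate_meiosis(5e6, 0.8)$breaks), 0)
  expect_lt(abs(mean(n_xo) - 0.8), 3 * sqrt(0.8 / 10000))

  set.seed(13); ga <- simulate_meiosis(5e6, 2)
  set.seed(13); gb <- simulate_meiosis(5e6, 2)
  expect_identical(ga, gb)
})

test_that("haplotype origin changes only at recorded crossovers", {
  set.seed(21)
  for (rep in 1:50) {
    g <- simulate_meiosis(1e6, 2)
    pos <- sort(runif(200, 0, 1e6))
    ori <- gamete_origin(g, pos)
    flips <- which(diff(ori) != 0)
    for (fl in flips) {
      expect_true(any(g$breaks > pos[fl] & g$breaks <= pos[fl + 1]))
    }
    # conversely, crossovers between successive query points flip parity
    seg <- findInterval(pos, g$breaks)
    expect_identical(ori, (g$start + seg) %% 2L)
  }
})

test_that("F2 cohorts segregate 1:2:1 with Poisson read depth", {
  cfg <- cross_config(layout = tiny_layout(2, 5e5), n_f2 = 1000,
                      depth_mean = 1, seq_error = 0, seed = 31)
  sim <- simulate_f2_cohort(cfg)

  for (s in 0:2) {
    frac <- mean(sim$truth$states == s)
    expected <- c(0.25, 0.5, 0.25)[s + 1]
    # bins within a sample are correlated; use the binomial SE at the
    # number of independent sample-chromosomes rather than of bins
    se_chrom <- sqrt(expected * (1 - expected) / (1000 * 2))
    expect_lt(abs(frac - expected), 3 * se_chrom)
  }

  depth <- sim$counts$cab + sim$counts$kaga
  se_depth <- sqrt(1 / length(depth))
  expect_lt(abs(mean(depth) - 1), 3 * se_depth)

  # deep error-free resequencing separates het sites (both alleles seen,
  # pooled ratio 0.5) from hom sites (a single allele only)
  cfg2 <- cross_config(layout = tiny_layout(1, 5e4), n_f2 = 200,
                       depth_mean = 30, seq_error = 0, seed = 32)
  sim2 <- simulate_f2_cohort(cfg2)
  tot2 <- sim2$counts$cab + sim2$counts$kaga
  fkaga <- sim2$counts$kaga / pmax(tot2, 1)
  # sites with both alleles seen are het: their pooled ratio ~ 0.5
  het <- fkaga > 0 & fkaga < 1 & tot2 > 0
  expect_lt(abs(mean(fkaga[het]) - 0.5), 0.02)
  # remaining covered sites are hom and carry a single allele
  expect_true(all(fkaga[!het & tot2 > 0] %in% c(0, 1)))

  expect_error(cross_config(n_f2 = 0), "n_f2")
})

test_that("zero depth yields all-zero counts without error", {
  cfg <- cross_config(layout = tiny_layout(1, 5e4), n_f2 = 5,
                      depth_mean = 0, seed = 33)
  sim <- simulate_f2_cohort(cfg)
  expect_true(all(sim$counts$cab == 0) && all(sim$counts$kaga == 0))
})

test_that("cohort simulation is reproducible under a fixed seed", {
  cfg <- cross_config(layout = tiny_layout(2, 1e5), n_f2 = 10, seed = 34)
  s1 <- simulate_f2_cohort(cfg)
  s2 <- simulate_f2_cohort(cfg)
  expect_identical(s1$truth$states, s2$truth$states)
  expect_identical(s1$counts$kaga, s2$counts$kaga)
  ph1 <- simulate_phenotypes(s1$truth, cfg)
  ph2 <- simulate_phenotypes(s2$truth, cfg)
  expect_identical(ph1, ph2)
})

test_that("phenotype model realizes the requested variance structure", {
  # null model: batch shift + residual noise only
  cfg <- cross_config(layout = tiny_layout(2, 1e5), n_f2 = 2000,
                      polygenic_var = 0, residual_var = 4,
                      batch_effects = c(a = 0), seed = 35)
  sim <- simulate_f2_cohort(cfg)
  ph <- simulate_phenotypes(sim$truth, cfg)
  expect_lt(abs(var(ph$y) / 4 - 1), 0.1)
  expect_lt(abs(mean(ph$y) - cfg$baseline), 0.2)

  # single QTL with target PVE 0.15 at n = 600
  lay <- tiny_layout(2, 2.5e5)
  pves <- vapply(1:30, function(i) {
    cfg <- cross_config(layout = lay, n_f2 = 600,
                        qtl_spec = data.frame(chrom = "chr1", bin = 20,
                                              pve = 0.15),
                        polygenic_var = 2.3, residual_var = 7.5,
                        batch_effects = c(a = 0), seed = 100 + i)
    sim <- simulate_f2_cohort(cfg)
    ph <- simulate_phenotypes(sim$truth, cfg)
    var(ph$qtl) / var(ph$y)
  }, 0)
  se <- sd(pves) / sqrt(length(pves))
  expect_lt(abs(mean(pves) - 0.15), 3 * se + 0.005)

  expect_error(
    cross_config(layout = lay, qtl_spec = data.frame(chrom = "chr9", bin = 1,
                                                     beta = 1)),
    "unknown chromosome")
})

test_that("oscillation traces follow the stated generative form", {
  expect_error(simulate_oscillation(0, duration_min = 300), "period")
  tr <- simulate_oscillation(55, duration_min = 300, interval_min = 10)
  expect_equal(nrow(tr), 31)
  expect_equal(tr$time_min, seq(0, 300, by = 10))

  # noiseless trace: discrete Fourier peak at 1/55 per min
  tr2 <- simulate_oscillation(55, amplitude = 1, duration_min = 1100,
                              interval_min = 10, noise_sd = 0)
  x <- tr2$intensity
  sp <- Mod(fft(x - mean(x)))[2:(length(x) %/% 2)]
  fpeak <- (which.max(sp)) / (length(x) * 10)
  expect_lt(abs(fpeak - 1 / 55), 1 / (length(x) * 10))

  # amplitude 0 leaves pure trend + noise
  tr3 <- simulate_oscillation(55, amplitude = 0, trend_slope = 2,
                              noise_sd = 0, duration_min = 100)
  expect_equal(tr3$intensity, 2 * tr3$time_min)
})
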