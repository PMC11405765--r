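---
title: "Methods: low-coverage F2 genotyping and developmental QTL mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: low-coverage F2 genotyping and developmental QTL mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`f2qtl` implements, end to end and on simulated data with known ground
truth, the statistical workflow used to map developmental traits — the
segmentation-clock period and presomitic mesoderm (PSM) size — in an F2
intercross between two divergent inbred fish strains ("Cab"-type and
"Kaga"-type):

1. **simulation** of F2 genomes, shallow sequencing reads and trait
   architectures (`simulate_*`);
2. **genotyping** of ~1× coverage samples into recombination blocks with a
   three-state Gaussian HMM on binned allele frequencies
   (`bin_allele_counts`, `decode_genotypes`, `fill_missing`);
3. **phenotyping** of oscillatory reporter traces by Morlet wavelet ridge
   extraction (`detrend_trace`, `normalize_envelope`, `cwt_ridge`,
   `summarize_period`);
4. **normalization** of phenotypes across imaging batches
   (`inverse_normalize`, `equate_batch_means`);
5. **association** of pseudo-SNP dosages with a leave-one-chromosome-out
   (LOCO) linear mixed model, with permutation and Bonferroni genome-wide
   thresholds (`association_scan`, `permutation_threshold`,
   `bonferroni_threshold`).

This vignette records the model assumptions, the tunable parameters with
their defaults and rationale, the numerical choices, and what the
simulation-based validation does and does not demonstrate.

# The synthetic cross

## Generative model

The two parents are fully inbred and homozygous-divergent at every panel
SNP, so the F1 is heterozygous everywhere and an F2 genome is the union of
two independent F1 gametes. A gamete is a crossover mosaic of the two
parental haplotypes: crossover counts per chromosome are
Poisson(`crossover_mean`), positions are uniform, and there is no
interference. `crossover_mean` defaults to 0.8 — fish linkage maps put
meiotic crossovers at fewer than one per chromosome per meiosis — giving
Poisson(1.6) expected crossovers per F2 chromosome (two gametes).

Sequencing is modelled at the allele-count level (no reads or alignment):
per sample and panel SNP, total depth is Poisson(`depth_mean`, default 1.0,
i.e. ~1× at panel sites), each read draws one of the two true alleles
(probability 1/2 each at heterozygous sites) and is flipped to the other
parental allele with probability `seq_error` (default 0.002, small but
non-zero so the HMM sees realistic contamination).

The default genome is deliberately desk-scale: 5 chromosomes × 5 Mb with
5-kb bins (5,000 bins) and SNP density 1/250 bp. This is ~1/100 of a real
~700-Mb teleost genome but preserves the quantity that drives genotyping
difficulty: ~20 informative SNPs, hence ~20 expected reads, per 5-kb bin
(the real data have ~2.2 M SNPs over ~140 k bins). Chromosome-scale
block structure is preserved by keeping `crossover_mean` per chromosome,
not per Mb.

## Trait model

Phenotypes follow `y = baseline + Σ β_q x_q + g + batch + ε`, with `x_q`
the dosage (0/1/2 Kaga alleles) at each configured QTL bin, `g` a
polygenic term, `batch` an additive shift, and `ε ~ N(0, residual_var)`.
The polygenic term is built from i.i.d. Normal effects on *all* genome
bins and rescaled so its realized variance equals `polygenic_var` exactly
— matching the additive-GRM assumption of the mixed model and making
heritability recovery tests stable. QTL effects can be given directly
(`beta`) or as a target fraction of the genetic-plus-residual variance
(`pve`), converted via `Var(x) = 1/2` (the Mendelian 1:2:1 variance).

Defaults put the trait on the scale of a clock period in minutes:
baseline 58 min, `polygenic_var = 2.3`, `residual_var = 7.5` (total SD
~3.1 min, matching the observed F2 spread of ~3.4 min), and two imaging
batches with a +3.5 min shift on the second microscope — the offset the
batch normalizations exist to remove. PVE is defined net of batch
variance because the inverse normalization removes batch differences
before mapping.

Real crosses between strains at the edge of speciation can show a
segregation skew (e.g. towards one homozygote, from partial hybrid
incompatibility); the simulator deliberately does *not* model this — it generates clean Mendelian 0.25/0.5/0.25 segregation,
which is the expectation the validation suite tests against.

## Oscillation traces

`simulate_oscillation` produces
`baseline + A·exp(rt)·sin(2πt/T) + slope·t + noise` sampled every 10 min,
mimicking a her7-type reporter: a decaying oscillation on a slow
fluorescence trend. The validation settings (amplitude 100 a.u., trend
0.5 a.u./min, envelope rate −0.002/min, noise SD 20 a.u. = 20% of
amplitude, 600 min duration) are chosen to resemble overnight time-lapse
recordings; they stress all three preprocessing steps at once.

# Genotype calling

Per bin, the Kaga-allele read frequency is `f = kaga/(kaga+cab)`; bins
with reads but no information content do not arise (any read is
informative), and **bins with zero reads get f = 0.5** — the
uninformative midpoint. Bins containing *no panel SNPs at all* are
treated differently: they can never receive reads, carry no information,
are excluded from decoding, and are filled afterwards from the previous
called bin (or the next one at a chromosome start). This reconciles the
0.5-assignment rule (zero reads) with the separate filling rule (no
SNPs). At the default panel density empty-panel bins are vanishingly rare
(P ≈ e⁻²⁰); the filling path is exercised by constructed tests.

The HMM has states 0/1/2 (hom-Cab / het / hom-Kaga), Gaussian emissions
with means 0, 0.5, 1 and a **shared variance of 0.8**, off-diagonal
transition probabilities of **1e-8**, and Mendelian initial probabilities
(0.25, 0.5, 0.25). The emission variance far exceeds the spread of `f`
within [0,1]; this is intentional: single-bin evidence is weak
(≤ ~0.6 log-likelihood units between states), so a state change must be
supported by a long run of consistent bins against the ~18.4-unit
transition penalty. Decoding uses the most-probable path (Viterbi, in
compiled code) rather than per-bin posteriors, because the object of
interest is the block segmentation itself. The consequences are
quantified by the test suite:

* ~96% of bins receive their true state at 1× depth;
* decoded state changes per chromosome track true crossovers from below
  (short double-crossover blocks flanked by the same state are absorbed
  when they span less than roughly 200 bins);
* the 90th percentile of changes per chromosome is ≤ 3, the block-count
  regime expected when crossovers average < 1 per gamete.

The method fixes the emission variance (0.8) and near-zero transitions;
emission means, the decoder, and the initial distribution are declared
package defaults, all configurable through `hmm_spec()`.

Sample-level QC excludes samples whose fraction of bins with ≥1 read
falls below 0.5 (`qc_samples`); the numeric threshold is a package default for what
counts as poor coverage, and at the default
depth it excludes nobody, while depth 0.01 samples are reliably caught.

# Period extraction

Raw traces are (1) detrended by subtracting a windowed-sinc (Blackman)
low-pass with cutoff period 100 min — the kernel spans the whole trace
and edges are padded by point reflection through the endpoints, which
continues linear trends exactly and avoids the triangle-wave artifacts of
mirror padding; (2) normalized by a sliding-window amplitude envelope
(window 150 min, envelope = √2 × windowed RMS, exact for a sinusoid);
(3) transformed with a Morlet continuous wavelet (ω₀ = 6, the standard
admissibility-respecting choice) evaluated on 200 *linearly spaced*
periods from 40 to 100 min via the FFT algorithm, with power normalized
by the trace variance so white noise has expectation ~1 at every scale.

The ridge is the per-timepoint maximum-power period. Samples closer to a
trace edge than the wavelet e-folding time (√2 × scale) are flagged as
outside the cone of influence (COI) and excluded from summaries. Two
summaries are taken over the first 300 min of reliable data, anchored at
the first inside-COI sample (the anchor choice is the package's): the **mean period** and the **intercept
period**, the y-intercept of an ordinary least-squares line through
(time-in-window, period) — OLS being the simplest reading of "fitted
line". Under the validation nuisance conditions all three true periods
(45/55/65 min) are recovered within ±1.5 min in every one of 50 seeded
traces each; the limiting factors are the 0.3-min period grid and
residual envelope distortion, not noise.

# Trait normalization

Two alternatives, selected per analysis:

* `inverse_normalize`: within each batch j of size N_j,
  `z = Φ⁻¹(rank/(N_j + 0.5))` with ascending average ranks (the tie rule is a package
  choice; ranks are taken on the raw values, 1-based ascending). This is rank-only — invariant to any strictly monotone
  transform — and removes batch location *and* scale entirely. It is the
  default input to the mapping stage.
* `equate_batch_means`: shifts each non-reference batch so its mean
  equals the reference batch mean, preserving units, within-batch
  variances and ranks.

The ~3.5-min between-microscope offset in the defaults is a property of
the simulated data, re-estimated from data by the analysis scripts —
never a constant of the method. `egg_volume` implements the
oblate-spheroid approximation `V = 4/3·π·b²·c`.

# Association mapping

Pseudo-SNPs are the 5-kb bins with their 0/1/2 state codes as dosages.
The GRM is the standardized (GCTA-style) estimator over polymorphic
markers, with allele frequencies taken from the analyzed sample (no
external reference exists for a synthetic cross). "Polymorphic" requires
variation, not just intermediate frequency — an all-heterozygous column
carries no relatedness information. For each chromosome, a LOCO GRM
excludes that chromosome's markers; variance components are REML-fitted
**once per LOCO GRM** and reused for all markers on the excluded
chromosome (standard MLMA-LOCO practice).

REML profiles the restricted likelihood over λ = σ²_g/σ²_e after an
eigendecomposition of the GRM, with a 41-point coarse grid on
log λ ∈ [−12, 8] followed by golden-section refinement — the grid
guarantees boundary optima (λ → 0) are found. The profiled likelihood is
verified against a dense-matrix oracle in the tests. Heritability is
reported as σ²_g·mean(diag G)/(σ²_g·mean(diag G)+σ²_e); with one cohort
it is weakly identified, so parameter-recovery tests assert averages over
replicates.

Per marker, the test is a Wald chi-square (1 df) from generalized least
squares in the rotated space, with the residual scale re-estimated per
marker from the weighted residual sum of squares (df = n − q − 1). This
choice makes the σ²_g = 0 case collapse *exactly* to ordinary least
squares (the statistic equals the squared OLS t). Monomorphic markers get
p = 1 and a flag rather than an error.

Significance thresholds:

* **permutation**: rows of (phenotype, covariates) are permuted jointly
  against the genotypes with 10 distinct seeds; each permutation gets a
  full LOCO scan; the threshold is the single lowest p-value across all
  permutations and markers (the literal "lowest P value from all 10
  permutations" rule, not a quantile of per-permutation minima);
* **Bonferroni**: 0.05 divided by the number of pseudo-SNPs in the model
  (always computed from the model, never hard-coded).

Runs of contiguous significant bins merge into loci with the minimum-p
bin as peak. Batch can enter either as a covariate or via prior
normalization; the default is prior inverse normalization with no
covariate.

# Pipeline, determinism, evaluation

`run_pipeline()` validates the whole nested configuration up front,
writes the resolved config verbatim, executes the stages in order
(simulate → genotype → traits → qtl → evaluate), names the failing stage
on error while retaining partial outputs, and emits a YAML + text report.
A single global seed deterministically derives per-stage seeds
(panel = seed, cohort = seed+1000, phenotypes = seed+2000, permutations =
seed+3000), so reruns are byte-identical — asserted on the written files.

`compare_to_truth()` scores per-bin genotype accuracy (truth at a bin is
the state at the bin *midpoint*; bins containing a crossover are
intrinsically mixed), breakpoint localization error (distance from each
called block boundary to the nearest true crossover), and QTL detection
(peak within 500 kb of the true bin).

# Validation scale and what it shows

The Monte-Carlo suite runs at sizes chosen to keep the full validation on
a laptop-class single core: genotype-composition checks on a 100–150
sample cohort; QTL power on 20 replicates of n = 600 with a PVE-0.15 QTL
over a polygenic background of h² = 0.2 (detection in ≥ 90% with the peak
within 500 kb); type-I control on 50 null replicates at n = 200 with no
QTL and no polygenic signal (a polygenic background is *true* signal —
its bins are genuinely associated — so it cannot serve as a
false-positive control); period recovery on 3 × 50 traces.

What passing does **not** show about real data: the simulator has no
segregation distortion, no reference bias, no variable SNP density or
coverage along the genome, no linked-QTL interference, no shared-F1
family structure beyond full sibs, and traces have stationary periods —
real clock periods drift, which is precisely why the intercept period
exists. Results on real crosses depend on those features; the package
demonstrates correctness of the machinery, not field performance.
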