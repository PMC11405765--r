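# f2qtl — low-coverage genotyping and developmental QTL mapping in F2 crosses

Segmentation timing in fish embryos — the period of the her7
segmentation-clock oscillator — and the size of the presomitic mesoderm
(PSM) are quantitative, polygenic traits. A classic way to dissect them is
an F2 intercross between two divergent inbred strains: every F2 genome is
a unique mosaic of the two parental haplotypes, produced by meiotic
recombination, and trait–genotype association over a few hundred embryos
localizes the causal loci. Doing this cheaply means sequencing each F2 at
~1× coverage, which rules out per-site genotype calls and motivates the
block-level machinery implemented here.

`f2qtl` provides that whole workflow as a tested R package plus a numbered
analysis pipeline, exercised end to end on simulated crosses with known
ground truth:

* **Simulation** — meioses with Poisson crossovers (mean 0.8 per
  chromosome, no interference), homozygous-divergent SNP panels,
  Poisson(1) per-site allele read counts with sequencing error, trait
  architectures (QTL + polygenic background + batch + noise), and raw
  oscillatory reporter traces.
* **Genotyping** — per 5-kb bin, the Kaga-allele read frequency
  f = kaga/(kaga+cab) (empty bins at 0.5) is decoded by a 3-state
  Gaussian HMM (means 0, 0.5, 1; shared variance 0.8; transition
  probability 1e-8), giving long recombination blocks; bins without panel
  SNPs are filled from the previous (else next) called bin; blocks become
  **pseudo-SNP** dosages (0/1/2 Kaga alleles).
* **Period extraction** — sinc detrending (cutoff 100 min), sliding-window
  envelope normalization (150 min), Morlet continuous wavelet transform
  (ω₀ = 6, 200 periods spanning 40–100 min), maximum-power ridge, and
  cone-of-influence-restricted summaries: the mean period and the
  intercept period (OLS y-intercept over a 300-min window).
* **Normalization** — per-batch rank-based inverse normal transform
  z = Φ⁻¹(rank/(N + 0.5)), or additive batch-mean equating; oblate-spheroid
  egg volume V = 4/3·π·b²·c.
* **Mapping** — standardized GRM
  G_jk = (1/M) Σᵢ (x_ij − 2pᵢ)(x_ik − 2pᵢ) / (2pᵢ(1−pᵢ)),
  leave-one-chromosome-out REML linear mixed model
  y = Wα + g + ε, g ~ N(0, σ²_g G_LOCO), per-marker Wald chi-square, a
  permutation genome-wide threshold (lowest p across 10 phenotype
  permutations) and a Bonferroni threshold (0.05 / #pseudo-SNPs).

See `vignettes/f2qtl-methods.Rmd` for assumptions, parameter rationale and
limitations.

## Worked example: the analysis pipeline

The `analysis/` scripts run the desk-scale study (150 F2s, 5 chromosomes
× 5 Mb, one PVE-0.15 clock-period QTL on chr3 at 2.5 Mb over a polygenic
background, two imaging batches 3.5 min apart):

```sh
Rscript analysis/01_simulate_cross.R
Rscript analysis/02_call_genotypes.R
Rscript analysis/03_extract_periods.R
Rscript analysis/04_normalize_traits.R
Rscript analysis/05_map_qtl.R
Rscript analysis/06_evaluate.R
```

Output of a complete run (fixed seed, abridged):

```
simulated 150 F2 genomes, 99907 panel SNPs, 5000 bins
true genotype fractions (hom-Cab/het/hom-Kaga): 0.252 0.492 0.256
called genotype fractions (hom-Cab/het/hom-Kaga): 0.246 0.507 0.248 — expectation 0.25/0.50/0.25
state changes per chromosome: mean 0.75 | 90th percentile 2
mean-period error (min): mean 0.008 | max abs 0.990
raw between-microscope offset (mean period): 3.95 min
invnorm residual batch offset: 1.39e-05
permutation threshold: 0.0011 | Bonferroni: 1e-05
significant loci: 8
genotype accuracy: 0.9564
QTL detection:  chr3 bin 500  peak_distance_bp 15000  detected TRUE
```

Reading this: the HMM recovers the Mendelian 1:2:1 block composition and
~96% of bin genotypes from 1× data; wavelet extraction returns each
embryo's period to within a minute; inverse normalization removes the
4-minute microscope offset; and the scan places its chr3 peak 15 kb
(three bins) from the true QTL, beyond both thresholds. The additional
significant bins (e.g. on chr5) trace back to the simulated *polygenic*
background — real trait signal spread over many bins, not false
positives; the null-simulation tests show the permutation threshold holds
when no genetic signal exists.

Equivalent programmatic entry points: `run_pipeline(config, out_dir)` for
the orchestrated run (YAML config, stage toggles, run report) and the
individual functions for each step.

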