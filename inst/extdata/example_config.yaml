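# Example pipeline configuration: a small 3-chromosome cross with one
# clock-period QTL. Any field omitted here takes the package default.
seed: 11
cross:
  n_chrom: 3
  chrom_length: 2500000
  n_f2: 60
  qtl:
    - chrom: chr2
      bin: 250
      pve: 0.25
traits:
  normalization: invnorm
qtl:
  n_perm: 5
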