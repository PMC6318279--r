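chrom: chrS
chrom_length: 2000000.0
snp_density: 0.002
read_length: 50.0
chip_fine_bin: 500.0
chip_coarse_bin: 10000.0
hic_bin: 100000.0
compartment_bin: 500000.0
repli_bin: 500000.0
chip_depth: 10.0
hic_depth: 60.0
meth_coverage: 20.0
expr_depth: 100.0
repli_depth: 100.0
planted_domains:
  start:
  - 160000.0
  - 820000.0
  - 1480000.0
  end:
  - 220000.0
  - 920000.0
  - 1620000.0
  k27_effect:
  - -1.0
  - -1.0
  - -1.0
  meth_percent:
  - 60.0
  - 60.0
  - 60.0
tad_set:
  start:
  - 0.0
  - 700000.0
  end:
  - 600000.0
  - 1700000.0
  restored:
  - yes
  - yes
compartment_profile:
- 1
- 1
- 1
- 1
mega_domain_boundary: 1000000.0
decay_exponent: -1.0
tad_factor: 3.0
compartment_factor: 2.0
mega_domain_factor: 0.2
noise_dispersion: 0.05
base_error_rate: 0.0
xi_k27_baseline: 1.0
seed: 7
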