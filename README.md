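# allelix

Allele-specific epigenome and 3D-genome analysis of the inactive X
chromosome, with a fully specified synthetic diploid chromosome for
validation.

## What problem this solves

In hybrid female cells whose X chromosomes derive from two divergent
strains, strain SNPs let sequencing reads be attributed to the active
(Xa) or inactive (Xi) X. Measuring how the Xi's chromatin state changes
under a perturbation — such as loss of the SMC-family protein SmcHD1,
which licenses sub-megabase *derepression domains* where Xi genes
reactivate, CpG methylation rises, H3K27me3 is lost, replication
advances and TADs/compartments return — requires a chain of
allele-aware analyses that are usually scattered across ad hoc
scripts. `allelix` packages that chain for analysts working on
X-inactivation or any allele-resolved chromatin problem:

* SNP-based read partitioning (hap1 / hap2 / unassigned / conflicting)
  and binned allelic count tracks;
* ChIP log2(IP/input) tracks (500 bp averaged into 10 kb) and the
  H3K27me3 depletion-domain caller (runs below 0, gaps ≤ 20 kb merged
  inclusively);
* peak allele-specificity scores `100·(Xi−Xa)/(Xi+Xa)` with the strict
  \>90% exclusivity rule;
* CpG methylation binning with a ≥3-read coverage filter, metagene
  profiles, per-site aggregation;
* copy-number-normalised allelic expression and the four-way Xi gene
  classification (escapee / dependent / partial / independent) by
  exact binomial allelic-fraction tests with BH correction;
* Hi-C: two-stage down-sampling/equalisation, Knight–Ruiz balancing
  (row sums uniform to 1e-6), distance-decay slopes, insulation scores
  (500 kb window, 200 kb delta, "mean" normalisation), A/B compartment
  eigenvectors from the O/E correlation matrix, and the TAD
  re-establishment score `(C_mut − C_wt)/C_wt` with quartile classes;
* Repli-seq S/G1 ratio Z-scores and within/outside-domain timing-shift
  contrasts;
* Mann–Whitney rank-sum machinery (exact ≤ 20 without ties, tie- and
  continuity-corrected normal approximation otherwise), Bonferroni,
  bp-level Jaccard domain overlap.

A synthetic-data module plants all of these signals on a diploid
chromosome with known truth, so every stage is validated by parameter
recovery. The methods vignette
(`vignettes/allelix-methods.Rmd`) documents the models, defaults and
numerical choices.

## Worked example

```r
library(allelix)
cfg <- sim_config(seed = 1)   # 20 Mb synthetic chromosome
cfg
#> Synthetic diploid chromosome configuration
#>   chrS: 20.0 Mb, 12 planted derepression domains, 19 TADs (15 restored)
#>   SNP density 1/500 bp, seed 1
rep <- run_pipeline(cfg)
rep
#> Pipeline report (seed 1 )
#>   assignment: 9.7% reads assigned, accuracy 1.000
#>   depletion domains (mut Xi): 15, mean 135 kb, planted Jaccard 0.99
#>   methylation contrast p = 4.19e-118; expression contrast p = 6.47e-204
#>   gene classes recovered: 100.0%
#>   insulation shift p = 8.43e-07; EV r (Xa~Xi) wt 0.13 -> mut 0.45
#>   timing shift within-outside = 1.45 z (p = 1.12e-08)
```

Reading the report: ~10% of simulated reads cover an informative SNP
and every one of them is assigned to its true haplotype; the
depletion-domain caller recovers the planted sub-megabase domains at
base-pair Jaccard 0.99 (15 called domains, mean 135 kb); CpG
hypermethylation and gene reactivation concentrate inside those called
domains (rank-sum p far below 10⁻⁴); all planted gene classes are
recovered; TAD boundaries insulate significantly more deeply on the
mutant Xi than the wild-type Xi; the Xa–Xi compartment eigenvector
correlation rises from 0.13 to 0.45 when compartmentalisation is
restored; and replication timing inside derepression domains advances
by ~1.5 Z units. Passing `out_dir =` writes every stage's BED /
bedGraph / triplet-matrix / JSON outputs plus `report.json`.

A thin CLI over the same functions ships at `inst/cli/allelix`
(subcommands `run`, `simulate`, `assign`, `chip`, `methyl`,
`insulation`, `balance`, `repli`, `contrast`).

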