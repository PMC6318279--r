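---
title: "Methods: allele-specific analysis of inactive-X chromatin with allelix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific analysis of inactive-X chromatin with allelix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allelix)
```

## The problem

In female hybrid cells whose two X chromosomes come from genetically
distant strains, strain-distinguishing SNPs allow sequencing reads to be
attributed to the active (Xa) or inactive (Xi) X. The Xi of such cells
carries a distinctive chromatin state: chromosome-wide gene silencing,
CpG hypomethylation with hypermethylated CpG islands, large blocks of
H3K27me3, late replication, and a Hi-C architecture of two mega-domains
separated by a hinge, with attenuated TADs and compartments. Loss of the
non-canonical SMC protein SmcHD1 partially reverses this state in
sub-megabase *derepression domains*: genes reactivate, CpG methylation
rises locally, H3K27me3 is depleted, replication timing advances, and
TADs and A/B compartments re-emerge.

`allelix` implements the full analysis chain needed to measure these
coupled changes allele-specifically, together with a synthetic diploid
chromosome generator that plants every one of them with known ground
truth, so that each analysis stage can be validated by parameter
recovery rather than by eye.

## Read partitioning

A read (or read pair, when a `pair_id` groups mates) is assigned by
comparing each observed base at a known SNP position with the two
haplotype alleles:

* **hap1** — at least one observation matches the haplotype-1 allele and
  none matches haplotype 2 (symmetrically for **hap2**);
* **conflicting** — observations support both haplotypes;
* **unassigned** — no informative SNP covered, or the observed base
  matches neither allele.

Conflicting reads are reported separately for diagnostics but pooled
with unassigned reads in binned tracks, preserving the three-way
hap1/hap2/unassigned split used downstream. Reads are counted into the
bin containing their start coordinate; for equal-length reads this is
unbiased and keeps counts conservative (each read counted exactly once).
Coordinates are 0-based half-open internally and BED on disk.

At the default SNP density of 1/500 bp and 50 bp reads, roughly 10% of
reads cover an informative SNP; the assignable fraction scales with
density and read length and is deliberately exposed as configuration
rather than fixed.

## ChIP enrichment and depletion domains

Enrichment is `log2((IP * s + c) / (input + c))` per 500 bp fine bin,
with pseudocount `c = 1` read and library factor `s` scaling IP to input
totals; fine values are averaged within 10 kb intervals (missing-aware:
fine bins with zero input are undefined, and an interval with no defined
fine bin is missing). In the pipeline the library factor is computed
from combined-haplotype totals: scaling within a single haplotype would
re-centre the Xi's chromosome-wide enrichment at zero and make a
"mean log2(IP/input) < 0" depletion definition vacuous.

H3K27me3 **depletion domains** are maximal runs of 10 kb intervals with
mean log2(IP/input) below 0; runs separated by at most 20 kb (an
*inclusive* bound, with missing bins counting toward the gap) are merged
transitively. No minimum length is imposed by default. The caller is
validated against an explicit brute-force scan on random tracks,
including the exact merge boundary.

Peak allele specificity is scored as `100 * (Xi - Xa) / (Xi + Xa)` on
input-corrected allelic read counts (+100 fully Xi-specific, -100 fully
Xa-specific); a peak is called chromosome-exclusive only when *strictly*
more than 90% of its allelic reads map to one haplotype. The input
correction divides each haplotype's IP count by its share of input
coverage over the peak; the exact correction used by peak-calling
pipelines varies, and this simple symmetric form is a documented choice.

## CpG methylation

Sites covered by fewer than 3 reads are discarded; a 10 kb bin's value
is the mean percent methylation of its retained sites. Metagene
profiles rescale each gene body to a fixed number of windows with
fixed-width flanks, reverse minus-strand genes, and average
missing-aware across genes.

## Allelic expression and the four silencing classes

Counts are normalised by chromosomal copy-number factors (median
per-bin allelic input coverage relative to a reference diploid
autosome, whose own factor is exactly 1) and by gene length, giving
reads per kb. Genes expressed on Xa are classified by three binomial
allelic-fraction tests (exact below 1000 informative counts, normal
approximation with continuity correction above; Benjamini–Hochberg
correction per test family at level 0.05):

1. *escape*: wild-type Xi counts above the silenced background, taken
   as 10% of Xa expression (the escape threshold, exposed as
   configuration);
2. *derepression*: mutant Xi counts above wild-type Xi counts, with the
   two conditions' sequencing depths (estimated from total Xa counts)
   as the null;
3. *restoration level*: mutant Xi versus mutant Xa against the
   copy-number-expected fraction (0.5), two-sided.

A gene is an **escapee** if test 1 rejects and its wild-type Xi/Xa
ratio is at or above the threshold; otherwise **dependent** if tests 2
rejects and 3 does not (reactivated to Xa level), **partial** if both
reject with mutant Xi below Xa, and **independent** otherwise. A
dedicated count test is used rather than a generic RNA-seq
differential-expression model because the allelic structure makes the
comparison within-gene and within-library: the gene's biological
expression rate is shared by its two alleles and cancels from the
allelic fraction, so only sampling noise remains. For the same reason
the classification depends on counts only through scale-free fractions
plus the tests' power; exact invariance under rescaling all counts by a
constant is impossible for any significance-based rule (power grows
with counts), and the test suite asserts 95% label stability under a
three-fold rescale instead.

## Hi-C

Samples are made comparable by two-stage subsampling without
replacement (multivariate hypergeometric draws): first every sample to
the smallest genome-wide total, then per-chromosome totals to the
per-chromosome minimum, normalising residual copy-number differences.
Matrices are balanced per chromosome with the Knight–Ruiz inner–outer
Newton iteration (conjugate-gradient inner solves, damping bounds 0.1
and 3), masking bins with zero marginals, to a relative row-sum
tolerance of 1e-6; the balanced matrix has unit row sums, verified in
tests by independent summation, and balancing a balanced matrix returns
unit weights.

The **insulation score** at bin *i* is the mean balanced contact in the
square pairing the `w` bins left of *i* with the `w` bins right
(`w` = 500 kb / bin size), reported as log2 of the raw value over the
chromosome-wide mean of raw values (the "mean" normalisation mode). The
delta track subtracts the mean score over the 200 kb left of *i* from
the mean over the 200 kb right; boundaries are score minima where delta
crosses zero from negative to positive with crossing amplitude of at
least 0.1 (configurable). This insulation-minimum caller stands in for
interactive TAD-boundary tools; the threshold is the one knob and is
deliberately exposed.

**Compartments**: observed/expected counts (expected = per-diagonal
mean over unmasked bins), Pearson correlation matrix of O/E columns,
first eigenvector, sign-oriented so that it correlates positively with
gene density; positive bins are A, negative B. Bins below the 0.5th
percentile of marginal coverage are masked — a coverage-percentile
stand-in for the coverage filters of standard compartment callers. Two
caveats are worth knowing. A compartment pattern that alternates with a
*single-bin* period is invisible to this estimator: each diagonal is
then purely same-label or purely cross-label, so the per-diagonal
expectation absorbs the signal; real compartments span several bins and
the synthetic default uses 2 Mb blocks of 500 kb bins. And on
inactive-X-like matrices the mega-domain hinge contributes block
structure of its own, so the first eigenvector of a wild-type Xi tracks
the hinge rather than compartments — which is precisely why the
Xa-versus-Xi eigenvector correlation rises when compartmentalisation is
restored in the mutant.

**Distance decay** P(s) is the mean balanced count per separation,
normalised to unit sum over s > 0; the slope is a least-squares fit of
log10 P on log10 s over a configurable range (default 200 kb – 5 Mb;
the range used for published slope values is generally not stated, so
it is exposed rather than fixed), with the fraction of far-cis
contacts (> 10 Mb) reported alongside.

**TAD re-establishment**: for each TAD, `C` is the sum of contacts
between bin pairs inside the TAD separated by more than 100 kb, in
equalised wild-type and mutant matrices; the score is
`(C_mut - C_wt) / C_wt` and TADs are classed by the quartiles of the
score distribution — weak below Q1, strong above Q3, medium between.
Because Q1 is by construction the 25th percentile, a cohort in which a
quarter of TADs are refractory is the regime in which "weak" aligns
with "not restored"; the synthetic default plants 75% of TADs as
restored accordingly, and with ~19 scored TADs one restored TAD
necessarily falls below Q1, bounding recovery at ~93%.

## Replication timing

The per-bin ratio is the read-number-normalised S/G1 ratio
`(s_i / S) / (g1_i / G)`; Z-scores are taken over the defined bins of
one chromosome-haplotype profile (the scoring scope, exposed as the
object boundary), and a bin enters the profile only when both fractions
contribute at least one read. Higher Z means earlier replication. The
S/G1 orientation is used throughout; the reciprocal labelling that
sometimes appears in figure legends is not followed. Timing shifts are
per-bin Z differences summarised within versus outside a domain set
with a rank-sum comparison; 100 kb bins are used for domain-scale
contrasts because sub-megabase domains only partially cover 500 kb
bins and the planted shift would otherwise be diluted.

## Rank tests

Group comparisons use the Mann–Whitney rank-sum test: exact null
distribution when the pooled sample is at most 20 without ties, normal
approximation with mid-rank tie correction and continuity correction
otherwise (the fully tied degenerate case reports p = 1). Exactness is
validated against full enumeration of all group assignments; the
normal branch's type-I error at the 0.05 level is checked on 10^4 null
replicates. Multiple domain-level comparisons use Bonferroni
(`min(1, m p)`), per-gene families Benjamini–Hochberg.

## The synthetic chromosome

The generator (`sim_config()` plus `simulate_*()`) emulates, on one
synthetic X-like chromosome (default 20 Mb) and a smaller autosome
control:

* SNPs at 1/500 bp — the order of magnitude of divergence between
  distantly related mouse strains;
* reads with per-bin sampling weights per haplotype and an optional
  per-observed-SNP base-error rate (errors flip to the *other* allele,
  the worst case for assignment);
* H3K27me3: Xi baseline log2(IP/input) of +1, dropping to -1 inside
  planted derepression domains in the mutant; input depth 10 reads per
  500 bp bin;
* CpG methylation: Xi baseline 15%, 60% inside planted domains,
  coverage 20 per site at 1 site / 200 bp;
* expression: a shared lognormal gene rate (CV 0.3) with Poisson
  conditional counts per allele; silenced alleles leak 2% of Xa,
  partial reactivation reaches 30%; the default 400-gene class mix is
  67 dependent / 163 partial / 28 escapee / 142 independent, and
  reactivated classes are placed inside the planted domains;
* Hi-C: power-law decay with exponent -1, TAD boost 3, same-compartment
  boost 2 (attenuated to 1 on the wild-type Xi), cross-hinge
  attenuation 0.2 on both Xi states, ~60-100 expected contacts at
  adjacent 100 kb bins; counts negative-binomial with dispersion 0.05
  (Poisson at 0), drawn on the upper triangle and mirrored;
* Repli-seq: flat wild-type Xi, two-fold S-phase enrichment inside
  planted domains in the mutant, 50-100 reads per bin.

Planted truth (domain coordinates, TAD restoration flags, gene classes,
read origins) is emitted separately from the analysis inputs and never
read by analysis code. Every generator reseeds deterministically from
the config seed plus a fixed per-assay offset, so a config reproduces
its outputs bit for bit.

What the generator does **not** emulate: mappability and GC biases, PCR
duplicates, fragment-level Hi-C artefacts (re-ligations, dangling
ends), trans-chromosomal contacts, base-call quality, isoform
structure, or cell-to-cell heterogeneity. Passing recovery tests on
this synthetic therefore demonstrates the correctness and statistical
behaviour of the analysis chain under the planted effect sizes — not
robustness to the alignment-level artefacts of real libraries, which
are assumed to be handled upstream of this package's inputs.

## Problem sizes and runtime choices

The shipped demonstrations use a 20 Mb chromosome: 40,000 fine ChIP
bins, 2,000 coarse bins, a 200 x 200 Hi-C matrix at 100 kb (aggregated
5-fold for compartments), ~100,000 CpG sites, 10^4 reads for the
assignment stage and cohorts of 120–400 genes. These sizes give every
stage hundreds to thousands of informative units while keeping the full
pipeline in seconds on one core; all of them scale up linearly through
the configuration if heavier validation is wanted.

## Known limitations

* The depletion-domain caller has no minimum-length filter by default;
  at low depth isolated noisy bins can contribute single-bin domains.
  `min_len` exists for users who want the filter.
* The compartment estimator reports the first eigenvector only; on
  hinge-dominated matrices the compartment signature may live in later
  eigenvectors (see above), which is a faithful property of the method
  rather than a defect, but worth remembering when interpreting
  wild-type Xi eigenvectors.
* The binomial allelic test treats copy-number factors as known;
  uncertainty in the factors is not propagated.
* Paired-end support is limited to label pooling via `pair_id`;
  insert-level effects are out of scope.
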