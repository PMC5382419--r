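---
title: "Quality control and imputation evaluation for low-coverage GBS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality control and imputation evaluation for low-coverage GBS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbskit)
```

## The problem

Genotyping-by-sequencing (GBS) reduces a large genome to the ends of
restriction fragments, sequences them at low depth across a multiplexed
cohort, and calls SNP genotypes from the resulting reads. In an outbred
diploid population this is statistically delicate: a heterozygote is only
visible if both chromosomes happen to be sampled by reads, so with `d`
reads the probability of miscalling a het as a homozygote is
`2 * (1/2)^d = (1/2)^(d-1)` — certain failure at one read, a coin flip at
two, still 1 in 4 at three. On top of this, restriction-site
polymorphism, methylation and library effects leave most sample-by-site
cells with no reads at all, so a typical raw call matrix is two-thirds
missing. The package provides the full evaluation workflow around such an
assay: enzyme choice by in-silico digestion, a simulator reproducing the
error structure of low-coverage calls, the two-step QC cascade,
concordance-based accuracy against an independent truth panel, and
masking-based evaluation of imputation.

## In-silico digestion

`digest()` cuts chromosomes at every top-strand occurrence of each
enzyme's IUPAC recognition site (site offset included: PstI = CTGCA^G,
MspI = C^CGG, ApeKI = G^CWGC). Fragments tile each chromosome exactly;
each end is labeled by the enzyme that produced it. In a two-enzyme
library only fragments with one rare-cutter end and one common-cutter end
amplify, which `sequenceable_fragments()` extracts. Matching is top-strand
only: the bundled sites are palindromic (GCWGC equals its own reverse
complement as an IUPAC set), so no cut is lost; `N` bases never match,
which treats assembly gaps conservatively. `fragments_from_coverage()`
estimates realized fragment counts from per-base coverage as maximal runs
of positive depth, assuming fragments are separated by zero-coverage
gaps — two adjacent fragments with touching coverage are merged by this
estimator, a known small downward bias.

The closed-form companion `expected_fragments(G, k, degeneracy)` gives
`G * degeneracy / 4^k` under uniform base composition. It identifies
fragment and cut-site counts; the per-chromosome end-fragment correction
is negligible at genome scale.

## The genotype-call simulator

`simulate_truth()` draws per-site minor allele frequencies (default
uniform on 0.05–0.5) and genotypes i.i.d. under Hardy–Weinberg
equilibrium. `simulate_block_truth()` adds linkage: consecutive blocks of
`block_length` markers (default 100, i.e. 100 kb at the default 1 kb
spacing — the scale over which LD persists in cattle-like populations)
carry 8 founder haplotypes, and each sample draws two per block. LD is
strong within a block and absent across block boundaries; this is the
structure the imputer exploits, and it deliberately omits recombination
gradients, relatedness and mutation.

`simulate_gbs_calls()` then generates, per sample-by-site cell:

* **Depth.** Zero (missing) with probability `zero_mass` (0.47),
  otherwise negative binomial with mean `4 * f_site` and dispersion 1,
  where `f_site` is a per-site gamma(1) coverage multiplier. The site
  multiplier reflects fragment-level amplification heterogeneity: the same
  fragment tends to amplify well (or poorly) in every sample. It is what
  spreads per-variant call rates over a wide range instead of
  concentrating them at the cohort mean; without it the second QC step's
  call-rate thresholds would retain essentially nothing. The defaults are
  calibrated so the average per-sample call rate is ≈ 0.35, typical of a
  conservatively called two-enzyme GBS assay, with most calls under 10
  reads.
* **Reads.** Each read samples one chromosome uniformly; with per-read
  error `error_rate` (default 0.01) it reports the other allele. The
  selective-primer artifact is modeled as per-cell allele dropout: with
  probability `dropout`, one allele of a het is entirely unamplified and
  every read comes from the other chromosome, producing a confident
  spurious homozygote.
* **Call and GQ.** Maximum-posterior genotype under the three-genotype
  read likelihood with a flat prior (ties toward the het, then hom-ref);
  `GQ = -10 log10(1 - posterior)`, rounded, capped at 99.

The caller's flat prior has a consequence worth knowing: GQ is
phred-calibrated for depth ≥ 2, but at depth 1 every call is a homozygote
with GQ 5 whose true error probability is the population het frequency
`E[2q(1-q)]` (0.365 under the default MAF spectrum) — slightly above the
nominal `10^-0.5 = 0.355` whenever hets exceed a third of truth. A second
consequence is that homozygous calls reach GQ ≥ 20 only at depth ≥ 7, so
the GQ filter is much harsher here than under callers with
frequency-informed priors; the tests account for both effects.

## The two-step QC cascade

Step one (`filter_calls()`) acts on calls: anything below the minimum
read depth, or below the minimum GQ when GQ filtering is on, becomes
missing. Step two (`filter_variants()`) recomputes per-variant statistics
on the filtered calls and retains variants by call rate (non-missing over
*all* panel samples), minor allele frequency (allele counts over
non-missing calls; denominator 2 × non-missing samples), at most
`max_alt` alternative alleles, polymorphism, single-nucleotide alleles,
and chromosome (X, Y, MT excluded by default). All comparisons are `>=`
on exact fractions — with 48 samples a 0.2 call-rate minimum means at
least 10 known genotypes. The GQ threshold is inclusive (`GQ >= 20`).
`dataset_grid()` derives one dataset per combination of thresholds, each
independently from the raw matrix, so retention counts are monotone in
every threshold by construction (and verified against a brute-force
oracle in the tests).

## Concordance and imputation evaluation

`concordance()` is directional: the designated truth panel (an array or
mass-spectrometry assay assumed error-free) defines correctness, pairs
with either side missing are excluded, and counts are stratified by the
truth class (hom-ref/het/hom-alt), which localizes artifacts — allele
dropout shows up as discordant heterozygotes. Shared markers are matched
on position with allele reconciliation: identical, swapped (codes
flipped), or complemented for unambiguous SNPs; A/T and C/G SNPs whose
swap is indistinguishable from a strand flip are excluded rather than
guessed.

For imputation, `combine_panels()` implements the dense-panel merging
design: anchor markers colliding with a GBS position are first removed
from the anchor, so every scored locus is imputed from GBS data (plus
surrounding anchors), never copied from the array; the pre-removal
overlap becomes the evaluation loci. `impute_knn()` fills each missing
call from the majority genotype of the `k = 5` best neighbours, ranked by
genotype agreement over a 21-marker window (at least 5 comparable
markers), with deterministic tie-breaking and a locus-major fallback.
It stands in for production imputers such as BEAGLE or FIMPUTE, which can
be slotted in via `impute_external()`'s VCF round-trip contract.
`evaluate_imputation()` scores only originally missing calls at
evaluation loci — the stricter of the two possible readings of "accuracy
of imputed genotypes"; scoring all calls would mix in the (higher)
accuracy of observed calls. Pedigree information is deliberately unused.

## What the synthetic experiments show — and what they cannot

The test suite reproduces, on 48-sample × 5000-site cohorts over five
seeds, the qualitative findings a practitioner relies on: accuracy rises
with the minimum read depth; simultaneous GQ filtering raises accuracy at
every depth level (at the cost of many calls); merging a dense error-free
panel improves imputation of missing GBS genotypes at every call-rate
threshold by 8–12 points; and imputation accuracy does not decrease as
the minimum call rate rises. Two scale caveats are documented rather than
hidden. First, the call-rate trend is evaluated on depth-filtered panels
without the GQ step: under the flat-prior caller, GQ ≥ 20 thins
high-call-rate GBS-only panels below the marker density at which a
window-based imputer sees any LD, an artifact of desk-scale cohorts, not
of the method. Second, trend comparisons are one-sided Monte-Carlo tests
(no decrease beyond 3 pooled binomial standard errors): with ~10⁴–10⁵
scored calls per cell, differences below ~1 point are at the resolution
limit. Absolute imputation accuracies of the k-NN stand-in (~52%
GBS-only, ~60–65% combined) are well below what haplotype-model imputers
achieve on real cattle data; the harness measures *designs* (panel
composition, thresholds), not state-of-the-art imputation.

Problem sizes were chosen to keep the full suite within a few minutes:
digestion oracles run on 10 kb random sequences, QC oracles on 100 × 1000
matrices, simulator-vs-theory agreement on 10⁵ het calls per depth, and
the trend experiments on five 48 × 5000 cohorts.

## Numerical and degenerate-input conventions

VCF coordinates are 1-based; fragment and coverage structures are 0-based
half-open. Missing genotypes are written `./.` with DP/GQ `.`; a FORMAT
lacking DP or GQ entirely defaults those layers to 0 with a warning, and
calls with unknown depth/quality fail any active threshold
(conservative). Genotypes are unphased throughout; `0/1` and `1|0`
normalize identically. A variant left with zero non-missing calls has
undefined MAF and fails any MAF threshold; concordance and imputation
scores over zero comparable pairs are `NA`, never silently 0 or 100.
Sample standard deviations use the n−1 denominator and are `NA` for a
single sample. All simulation functions are bit-reproducible under a
seed; the imputer is deterministic outright.
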