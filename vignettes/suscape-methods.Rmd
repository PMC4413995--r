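---
title: "Copy-number landscapes and copy-number phylogenetics with suscape"
author: "suscape authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number landscapes and copy-number phylogenetics with suscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suscape)
```

## The problem

Closely related populations — the motivating system is the genus *Sus*,
seven pig populations from Eurasia and island Southeast Asia that diverged
within the last few million years and hybridized repeatedly — differ not
only in SNPs but in the copy number of genomic segments. Two questions
drive this package: *where* does copy number vary between populations
(copy number variable regions, CNVRs), and *does the copy-number
landscape track the species phylogeny or the history of admixture?* The
interest in the second question comes from olfactory receptor (OR) genes:
if OR copy numbers resist homogenization by hybridization while other
loci do not, OR-overlapping CNVRs should recover the accepted species
tree where other CNVRs do not.

`suscape` implements the full analysis chain: read-depth copy-number
estimation, CNVR ascertainment, gene annotation with an OR partition,
rate comparison of binary copy-number differences (CND) against SNPs,
distance-based trees, and Bayesian phylogenetics on discretized copy
numbers under the Mkv model with constrained topologies compared by
stepping-stone marginal likelihoods. A synthetic-cohort generator
reproduces the statistical structure of the study design so that every
stage is testable without the original sequence data.

## Read-depth copy-number estimation

The read-depth (RD) method infers the copy number of a segment from its
relative coverage. The genome (repeat-masked) is tiled into 1-kb bins;
bins with fewer than 300 unmasked bases are dropped (`build_bins()`).
Per-bin mean depth is computed per individual and the two individuals of
a population are pooled by summation before any correction
(`pool_population()`), trading individual resolution for sensitivity.

Two systematic effects are corrected:

* **GC bias.** Sequencing coverage is depressed at GC extremes. Bins are
  stratified by GC in fixed strata of width 0.01; each stratum's depth is
  rescaled by (reference mean) / (stratum reference mean). Strata with
  fewer than 100 reference bins inherit the nearest populated stratum's
  factor, and the factors are renormalized so the reference-set mean is
  preserved exactly (`correct_gc()`). The reference set defaults to bins
  provisionally classified diploid (see below), since genic seed regions
  are GC-atypical; `gc_reference = "all"` and `"seed"` are available.
* **Diploid calibration.** CN = 2 × depth / d₂ needs the diploid depth
  d₂. No diploid truth is available a priori, so calibration is
  two-stage (`calibrate_diploid()`): stage 1 averages depth over seed
  "assumed diploid" regions (in the real workflow, 1:1 orthologous genic
  regions across distant mammals); stage 2 reclassifies every bin with
  provisional CN in [1.5, 2.5) as diploid and recomputes d₂ over that
  much larger, less GC-biased set. Exactly one recalculation is
  performed. The window [1.5, 2.5) is symmetric around 2 on the low side
  and exclusive at 2.5 to mesh with the multi-copy seed threshold below.

CN estimation is invariant to global depth rescaling, which the test
suite checks as a property.

## From bins to CNVRs

Per population, **multi-copy regions (MCRs)** are maximal runs of at
least 6 genomically consecutive retained bins with CN ≥ 2.5
(`call_mcrs()`); a masked (dropped) bin breaks a run, as repeats break
region contiguity in the real genome. MCRs are merged across populations
by transitive single-linkage union of overlapping intervals
(`merge_mcrs()`), each merged region is scored with its per-population
mean CN (`score_regions()`), and regions whose per-population CN has a
sample standard deviation (n − 1 denominator) of at least 0.7 are
**CNVRs** (`ascertain_cnvrs()`). The sd is taken across the seven
population-level values, matching the pooled-track workflow; raising the
threshold can only shrink the CNVR set (tested as a monotonicity
property). Group-specific ascertainment re-runs the chain within a
population subset (`group_ascertain()`), with leave-out resampling
(`group_resample()`) for taxon-sampling robustness.

The CN ≥ 2.5 seed makes ascertainment amplification-driven by design;
deletions remain visible as low CN in the scored region matrix but are
not an ascertainment class of their own.

## Annotation and the OR partition

A gene qualifies as CNVR-overlapping when at least 70% of its length is
covered by the union of CNVR intervals; its CN vector is copied from the
single CNVR it overlaps most (`overlap_genes()`). CNVRs then partition
into CNVR-OR (≥ 1 qualifying OR gene; mixed CNVRs go here — the
partition must be disjoint and no tie rule is dictated by the biology,
so OR precedence was chosen and documented), CNVR-nonOR (qualifying
genes, none OR) and CNVR-ALL (`partition_by_class()`).

## Rates and distance trees

Copy-number differences are deliberately binarized: a locus counts for a
pair of samples iff |CN difference| ≥ 2, so a jump from 2 to 10 copies
counts once and the CND rate is conservative (`binary_cnd()`). Rates
divide counts by the partition's locus count; the SNP rate divides
pairwise differences by callable diploid sites (`snp_rate()`); their
ratio is reported as mean, minimum and maximum over sample pairs
(`rate_ratio()`), since pairs differ and a single number hides that
spread.

`nj_tree()` is a from-scratch Saitou–Nei neighbor joining with the
standard Q criterion, deterministic lexicographic tie-breaking and
negative-branch clamping (deficit moved to the sibling so path lengths
are preserved). It reproduces additive matrices exactly, which the tests
verify against brute-force topology enumeration for 5–6 taxa.
`cn_cluster()` wraps `stats::hclust` (complete linkage on Euclidean CN
distances) — the clustering step uses the established implementation on
purpose; only the distance definitions are this package's contribution.

## Bayesian phylogenetics on copy numbers

Copy numbers are continuous; the Mkv model wants a small discrete state
space. Each locus is range-normalized and rounded to states 0–9:

state = round(((CN − CN_min) / (CN_max − CN_min)) × 9)

with halves rounded away from zero (`round()`'s half-to-even would make
state boundaries parity-dependent; the rule is pinned and tested). The
per-locus min maps to 0 and max to 9, so 10 states; invariant loci are
skipped with a warning.

The **Mkv likelihood** (`mkv_log_likelihood()`) is the symmetric k-state
Markov model with transition probabilities
P_same(t) = 1/k + ((k−1)/k)·e^(−kt/(k−1)) and
P_diff(t) = (1/k)(1 − e^(−kt/(k−1))), uniform root frequencies, computed
by Felsenstein pruning (Rcpp, exploiting the two-value structure of the
transition matrix for O(k) messages), and conditioned on characters
being variable: each site likelihood is divided by (1 − Σ constant
pattern likelihoods). A single symmetric rate class is used throughout —
the hierarchical rate-class machinery of general-purpose samplers
collapses to this in the regime relevant here, and one rate class keeps
the marginal-likelihood comparisons interpretable.

**MCMC** (`mkv_mcmc()`) is Metropolis–Hastings over topologies (uniform
prior over constraint-compatible topologies; random NNI proposals with
hard rejection of constraint violations) and branch lengths
(Exponential(10) prior, so mean 0.1 expected substitutions per
character; multiplier proposals). Constraints are clades required to be
monophyletic in the unrooted (split) sense, validated as nested or
disjoint. A data-free run samples the prior, which the tests use to
verify the sampler against the known prior mean.

**Stepping-stone marginal likelihoods** (`stepping_stone()`,
`stepping_stone_mkv()`) use a ladder of power posteriors at
Beta(0.3, 1) quantiles, β_j = (j/K)^(1/0.3). The ladder is traversed
from the posterior down to the prior, with the estimator
ln m̂ = Σ_j ln[(1/n) Σ_i L(θ_i^{(j)})^(β_{j+1}−β_j)] and per-rung Monte
Carlo standard errors. Because topology space is multimodal, the ladder
is seeded by a short multi-start mode-finding phase at β = 1, one start
being the NJ topology on Hamming distances of the discrete states when
it satisfies the constraints. The generic estimator is exercised against
a conjugate closed form (θ ~ U(0,1), L = θ(1−θ), ln m = ln B(2,2)) in
the tests. `compare_models()` tabulates delta-lnL relative to the best
model; `sus_constraint_models()` predefines the null (two major clades)
and four cross-clade admixture constraints for the seven-population
cohort.

## The synthetic cohort generator

The generator (`simulate_cohort()` and its parts) emulates the study
conditions, not any particular dataset:

* **Genome** (`simulate_genome()`): one or more chromosomes, ~40% repeat
  mask from uniformly placed geometric-length intervals, per-bin GC from
  an AR(1) process (mean 0.45, sd 0.07, lag-1 correlation 0.98, clamped
  to [0.2, 0.7]) so GC strata are realistically autocorrelated and well
  populated.
* **Copy-number truth** (`evolve_cn_on_tree()`): a rooted species tree
  over the seven populations (branch lengths in expected events per
  locus) with a root CN drawn from {2..6} per locus and a ±step
  birth-death walk floored at 0. `step_size = 1` is the classical
  single-copy step process; the cohort level defaults to `step_size = 2`
  because the tips are populations: a gain or loss fixed in a population
  adds or removes one copy per haplotype and therefore shifts diploid CN
  by two — exactly the unit the |ΔCN| ≥ 2 binarization counts once.
  Loci are OR or non-OR; admixture edges (donor → recipient with a
  proportion) overwrite recipient states at non-OR loci only,
  implementing the hypothesis under test (OR loci resist admixture) as a
  generative assumption whose downstream signature the tests can then
  check.
* **Depth** (`simulate_depth_track()`): per-bin read counts are negative
  binomial with mean coverage × (CN/2) × g(GC) × unmasked/read-length
  and dispersion 30, converted to mean per-base depth. Simulating counts
  rather than raw depth gives the variance a 1-kb bin actually has
  (~50–100 reads per bin), which matters for false-positive MCR seeds.
  The default bias curve is g(GC) = exp(−4(GC − 0.45)²), rescaled to
  unit mean — the smooth unimodal shape reported for Illumina coverage.
  The noise model itself is a package choice; no specific noise law is
  dictated by the RD method.
* **Individuals**: each individual hangs off its population tip by a
  private stub branch (default 0.02) for both the CN and the SNP
  process, so within-population pairs accumulate differences on the
  same footing as between-population pairs.
* **SNPs** (`simulate_genotypes()`): a symmetric two-state flip process
  with branch flip probability (1 − e^(−2rl))/2, giving pairwise
  difference fractions ≈ rate × path length for small rates.
* **Planted regions**: 60 regions of 8–20 consecutive retained bins.
  Planted truth profiles are conditioned to be unambiguous variable
  regions: cross-population sd ≥ 1 (at least two event-steps of
  dispersion) and at least one population at CN ≥ 4. Profiles whose true
  sd sits exactly at the 0.7 ascertainment boundary are unrecoverable in
  principle — one flanking bin picked up by the merged interval dilutes
  the scored sd below threshold — so they are out of scope for recovery
  experiments by design.

What the generator does *not* emulate: read-level artifacts
(mappability, multi-mapping, paired-end structure), segmental-duplication
architecture, deletion-biased regions, sex chromosomes, or
reference-genome errors. Passing recovery tests therefore demonstrates
the pipeline's statistical correctness under its own assumptions, not
calling performance on real short-read data.

## Numerical choices and problem sizes

* Coordinates are 0-based half-open internally and in BED output; all
  interval readers sort their input.
* GC strata: width 0.01, 100-bin minimum, nearest-stratum fallback.
* NJ ties are broken lexicographically by cluster label (a cluster is
  labelled by its smallest member), making results order-independent.
* The Mkv pruning rescales partial likelihoods when they drop below
  1e-200 and reports −Inf (rather than failing) for zero-probability
  configurations such as variable sites on an all-zero-length tree.
* Branch-length prior Exponential(10) and the multiplier/NNI proposal
  mix are this package's choices; no specific sampler configuration is
  canonical for this model class.
* Default verification sizes, chosen to make results statistically
  decisive at desk scale: 20-Mb single-chromosome cohorts with 60
  planted regions for recovery; 1408 loci / 10⁶ sites for the rate
  ratio; 300 variable characters and a 10-rung ladder with 1500 samples
  per rung for model selection; 20 replicate cohorts for the tree
  recovery comparison. The full-length ladder default (50 rungs) matches
  common practice for production marginal-likelihood estimates.

## Known limitations

* Pooling two individuals halves the variance but makes the "population
  CN" a two-individual average; scored CN is compared against that
  average, and within-population polymorphism shows up as half-integer
  truth.
* Ascertainment is amplification-driven (CN ≥ 2.5 seeds); deletion-only
  CNVRs are not called as regions.
* The Mkv state space discards locus-specific scale: state 9 means "this
  locus's maximum", not a specific copy number, so branch lengths are in
  expected state changes, not copy-number events.
* Stepping-stone estimates at reduced rung counts carry a few lnL units
  of seed-to-seed spread; model rankings in the tests rest on margins an
  order of magnitude larger.
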