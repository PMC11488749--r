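---
title: "Detecting hidden genetic lineages: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting hidden genetic lineages: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lineagescan)
```

## The problem

Many nominal species — salamanders are a canonical example — harbour deeply
divergent mitochondrial lineages that taxonomy has not yet recognised.
`lineagescan` implements a complete screening pipeline for such *hidden
genetic lineages* from single-locus barcode data (COI, cytb): alignment
quality control, three single-locus species-delimitation methods, consensus
classification of each species as hidden / not hidden, assembly of
geographic, climatic and life-history predictors per species, and a
random-forest classifier that asks which traits predict hidden diversity.
Because the interesting guarantees are statistical, every stage can be
exercised against a synthetic-world generator with planted ground truth.

## Sequence quality control

Nucleotide diversity π is the mean over unordered sequence pairs of the
proportion of differing *comparable* sites; a site is comparable for a pair
only when both residues are unambiguous bases (`A/C/G/T`) — gaps, `N` and
ambiguity codes are excluded pairwise. Across a collection of alignments the
π values are screened against their empirical 2.5% / 97.5% quantiles
(linear-interpolation quantiles, `stats::quantile` type 7; the common
default of mainstream numeric stacks). "Short" sequences — those missing
50% or more of the trailing `ceiling(L/2)` alignment columns, where
*missing* means any symbol outside `A/C/G/T` — are removed before π is
computed. For odd alignment lengths the trailing half is the larger half;
the filter is idempotent.

## Species delimitation

Three methods vote per species × locus; a vote is "hidden" exactly when the
method infers more than one lineage.

**Barcode-gap partitioning (`gap_delimit`).** For each prior `P` on the
maximum intraspecific divergence (ten log-spaced values in [0.001, 0.1]),
the sorted distinct p-distances are scanned from below for the first
significant gap: wider than 1.5× the mean gap width below it (the prior
itself serves as the reference when no gaps precede it), not entirely below
`P`, and wider than `max(P, min_gap)`. The distance graph is cut at the
gap's lower edge, groups are connected components (equivalently:
single-linkage clusters), and the scan recurses within groups. The reported
count is the mode across priors, ties resolved toward fewer lineages — the
conservative reading of a multi-prior sweep.

**Merge-path gap scoring (`merge_delimit`).** Partitions induced by the
single-linkage merge path (2 to n−1 groups) are scored by
`min between-group distance − max within-group distance`; the best-scoring
partition is reported if its score exceeds both `min_rel_gap` (default 1)
times the maximum within-group distance and the absolute floor `min_gap`.
This is a deliberate simplification of composite-score merge methods, not a
reimplementation of any published score.

**Why an absolute floor?** Coalescent variation inside a single population
routinely produces *relatively* large discontinuities: groups of identical
haplotypes have zero within-group distance, so any positive between-group
distance is an "infinite" relative gap, and deep within-population
coalescences mimic shallow species splits. A floor of `min_gap = 0.02`
substitutions/site — the conventional barcode divergence threshold for
mitochondrial protein-coding loci — screens both artefacts. The price is
insensitivity to genuinely shallow splits (d < ~0.03 substitutions/site);
the parameter is exposed on both functions.

**Single-threshold GMYC (`gmyc_fit`).** On an ultrametric tree with node
heights measured from the tips, a threshold T separates a
diversification (Yule-like) regime above from within-population coalescence
below. With k(t) between-species lineages and n_j(t) lineages inside
cluster j alive at height t, the combined branching rate is

$$b(t) = \lambda_{div}\,k(t) + \lambda_{coal}\sum_j n_j(t)\,(n_j(t)-1),$$

with both rate exponents fixed at one (the linear-rate model). The
likelihood is the product over internode intervals of
\(b\,e^{-b\,x}\); because only one process can generate events on each side
of T, the per-process maximum-likelihood rates are closed-form
(events / process-weighted time). T is profiled over the midpoints between
consecutive distinct node heights, plus a degenerate threshold above the
root under which the model collapses to the single-coalescent null — so the
alternative always nests the null and the likelihood ratio is non-negative.

Implementation notes:

* The full threshold profile is computed in O(n²) using the identity
  \(\sum_j n_j(n_j-1) = L_t(L_t-1) - N_t(T)\), where \(N_t(T)\) counts
  ordered pairs of contemporaneous lineages whose MRCA is older than T;
  pairs merging at node v contribute \(2\,a_v(t)\,b_v(t)\) (left × right
  subtree lineage counts) and are suffix-summed over thresholds. An
  interval-sweep reference implementation is kept and the two are asserted
  equal in the tests.
* The LR statistic is referred to χ² with **3** degrees of freedom (two
  rates plus the threshold, the classical convention for this model).
  Under a simulated single-population coalescent null the 3-df reference
  holds the nominal level (~2–3% rejections at α = 0.05 over 200
  replicates) where a 2-df reference is anticonservative (~12–14%).
* Zero-length branches (identical haplotypes) are outside the model: they
  give positive event counts with zero waiting-time exposure, so the rate
  MLE diverges. Identical haplotypes are therefore collapsed to one
  representative before tree building (standard GMYC practice) and any
  remaining tied node heights receive a deterministic minimum-separation
  adjustment of about 10⁻⁶ of the tree depth.
* The GMYC is fitted **once per locus on the pooled tree of all species**
  (the survey design this pipeline reproduces used one chronogram per gene);
  each species' lineage count is the number of fitted entities among its own
  tips. A pooled tree is also what gives the LR test its power: with only
  two planted clusters a single long root wait is exactly what a
  single-population coalescent predicts, and power is ~40%, whereas with
  many species sharing one threshold the test is essentially always
  significant. Per-species fitting remains available via
  `delimit_all(..., gmyc_pooled = FALSE)`.

Trees come from UPGMA (`hclust` average linkage, heights halved) on JC69
distances: the chronograms the threshold model expects are ultrametric, and
UPGMA preserves exactly that property; divergence-time accuracy is neither
needed nor claimed. Saturated pairs (p ≥ 0.75) are flagged and excluded
from tree building.

## Consensus classification

Votes are pooled across loci and methods with equal weight. *All-agree*
labels a species only under unanimity and excludes conflicted species;
*majority-rules* takes the majority vote and never excludes. Exact ties go
to "hidden": the scheme exists to flag candidates for further taxonomic
evaluation, so ties err toward flagging. All-agree labels are provably a
subset of the majority labels restricted to non-excluded species, and the
tests assert that nesting.

## Predictors and imputation

Per species: the mean and sample SD (n−1; undefined and flagged for a
single point) of each environmental layer at the occurrence coordinates
(nearest-cell lookup, no interpolation), the min/max/mean/length of latitude
and longitude (plain arithmetic, no antimeridian wrapping — the study
region emulated here is far from ±180°), and life-history traits
(reproductive strategy, habitat, body size) with missing-at-random gaps.

Missing cells are completed by chained-equation predictive mean matching:
each target column is regressed on all others over the complete cases,
coefficients are drawn from their sampling distribution (normal draw around
the estimate with a scaled inverse-χ² variance draw), each missing case's
prediction is matched to its `k_donors = 5` nearest observed predictions,
and one donor's *observed* value is sampled — so imputed numerics are always
values actually seen in the data. Categorical columns use a
multinomial-logistic draw. Columns are swept until the imputed means
stabilise (at most 10 sweeps), `m = 15` independent completions are
generated, and pooling takes the numeric mean / categorical mode (ties to
the lexicographically smallest). Observed cells are never altered.

## Random-forest evaluation

Predictors with absolute Pearson correlation at or above the cutoff
(0.75 / 0.85 / 0.90, or none) are removed greedily: from the worst pair,
the member with the larger mean absolute correlation to everything else
goes (ties lexicographic). The data are split 70/30 with per-class
stratification; `mtry` is tuned over a grid centred on ⌊√p⌋ by 10-fold
cross-validation with five repeats optimising ROC AUC (via `caret`), and
the final 500-tree forest reports permutation (MDA) and Gini importances.

Evaluation follows the exact-statistics convention: accuracy with its
Clopper–Pearson 95% interval (Beta quantiles), the no-information rate (the
majority-class fraction of the *test* set), the one-sided exact binomial
p-value of accuracy exceeding the NIR, and positive/negative predictive
values with "hidden" as the positive class. These closed-form statistics
reproduce published model tables to printed precision and are verified in
the tests against brute-force tail sums and CDF inversion. Top-10
importance lists are tallied by predictor kind (SD / mean / geographic /
life-history), and the top predictors get a Kruskal–Wallis follow-up
(`stats::kruskal.test`, tie-corrected H, χ² with 1 df for two groups).

## The synthetic world

`generate_world()` plants known structure under one seed:

* **Sequences.** Each locus has a shared root sequence;
  species ancestors sit `species_divergence = 0.15` substitutions/site away
  (pairwise interspecific p-distance ≈ 0.25, comfortably below JC69
  saturation). Hidden species (exactly `round(n_species × p_hidden)` of
  them) carry `k_lineages = 2` lineage ancestors with *disjoint* private
  substitutions totalling `d_between = 0.08` between lineages — a barcode
  gap exists by construction. Within a lineage, sequences evolve on a
  simulated Kingman coalescent genealogy scaled to expected pairwise
  diversity `theta_within = 0.005`, with exact Jukes–Cantor per-branch
  substitution probabilities. The coalescent genealogy (rather than
  independent per-sequence mutation) matters: star-shaped within-lineage
  trees violate the GMYC's coalescent assumption badly enough to make it
  oversplit single populations.
* **Defaults as study conditions.** 80 species, 60% hidden, 20 sequences
  per species (each georeferenced), a first locus always present and a
  second in ~25% of species — mirroring a survey of ~83 species averaging
  ~20 sequences with sparse second-locus coverage. The gap ratio
  `d_between/theta_within = 16` is the "clearly delimitable" regime the
  benchmark properties target.
* **Geography and environment.** Occurrence points come from per-lineage
  Gaussian clusters whose centres sit on a circle around the species
  centre. Radius and within-cluster spread are chosen so the *marginal*
  per-axis SD is exactly `base_spread_deg` for a not-hidden species and
  `env_sd_hidden_multiplier ×` that (default 3×) for a hidden one — at
  multiplier 1 the class signal vanishes identically, giving a clean
  negative control. Environmental layers are smooth low-frequency random
  fields (four bioclim-like layers, a productivity layer, two nuisance
  layers); the class signal enters *only* through occurrence spread, never
  through the grids.
* **What it does not emulate.** Real demography (migration, expansion),
  recombination, selection, hybridisation, spatially autocorrelated
  sampling bias, map projections, or real GIS layers. Passing benchmarks
  show the pipeline recovers planted structure of this idealised kind; they
  do not certify performance on real occurrence data, where sampling is far
  messier.

## Numerical choices and degenerate inputs

* Quantiles: type 7 everywhere; distances: p-distance for the gap methods,
  JC69 for trees (configurable).
* UPGMA ties break deterministically (tips sorted lexicographically before
  clustering); identical alignments always yield one lineage by every
  method.
* Graph cuts are inclusive of the cut height up to a relative 10⁻¹²
  epsilon (floating-point equality at single-linkage merge heights).
* Degenerate GMYC inputs — fewer than three unique haplotypes, or all node
  heights equal — return the null model (one lineage) rather than erroring;
  non-ultrametric or non-binary trees are rejected.
* PMM requires at least `max(10, k_donors + 1)` observed values per
  imputable column and refuses fully missing rows; rank-deficient design
  matrices fall back to the pivoted rank from the QR decomposition with a
  small ridge.

## Problem sizes used by the tests and the acceptance script

The test suite and `scripts/acceptance.R` run: delimitation-recovery sweeps
over eight and four 20-species worlds respectively (~100–160 hidden-species
decisions per method), 200 single-population coalescent replicates for the
GMYC null calibration, and one full pipeline at the default 80-species (and,
in the acceptance test, a 200-species) scale. These sizes keep every
stochastic assertion's sampling error well below its margin while the whole
suite completes in a few minutes.

## Known limitations

* Single-locus mitochondrial evidence only; the consensus is a screening
  label, not a species hypothesis.
* The absolute `min_gap` floor ties the distance methods to
  barcode-scale divergences; lineages separated by less than ~0.03
  substitutions/site will not be flagged.
* UPGMA branch lengths are not time-calibrated; GMYC thresholds are in
  distance units and not comparable across loci with different rates.
* The merge method is a simplified gap score, intentionally conservative;
  it reports at most the single best-supported partition.
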