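---
title: "Methods: SNP-array phylogenies, ascertainment bias, and the intensity route"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP-array phylogenies, ascertainment bias, and the intensity route}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arrayphylo)
```

## The problem

SNP genotyping arrays are designed from variants discovered in a small panel
of individuals, usually dominated by one taxon of economic interest. Used
across a whole genus, two things go wrong:

1. **Ascertainment bias.** SNPs were selected to segregate in the focal
   taxon. The focal taxon therefore shows an excess of intermediate-frequency
   alleles, while distantly related taxa are fixed at most assayed sites.
   Distances computed from genotype calls -- here pairwise Weir--Cockerham
   \(F_{ST}\) -- are distorted in a structured way: pairs of non-focal taxa
   take extreme values (many shared or opposed fixations), while every pair
   involving the focal taxon lands in a compressed intermediate band. The
   compressed band can pull the focal taxon to the wrong place in a
   distance-based phylogeny.

2. **Probe-affinity loss.** Probes were designed against the focal taxon's
   genome. With increasing divergence, off-target variants (OTVs) at or near
   the probe site weaken hybridization. This degrades genotype calls for
   diverged taxa, but it also means that raw two-channel intensities carry
   divergence information that the categorical calls discard.

The package implements both analysis routes so they can be compared on data
where the truth is known: the **genotype route** (call-level QC, \(F_{ST}\),
neighbor joining) and the **intensity route** (per-SNP summary statistics of
the normalized channels treated as "quantitative genotypes", per-species
medians, Euclidean distances, neighbor joining).

## The genotype route

**Filters.** Calls with GenCall score < 0.2 are set missing; SNPs with
GenTrain < 0.3, more than 20% missing calls, or minor allele frequency
< 0.05 are dropped, in that fixed order (the order changes survivor counts,
so it is part of the contract; all comparisons are strict). LD pruning uses
the PLINK-style windowed scan (window 10, shift 3, \(r^2 > 0.5\) removes the
lower-MAF member, ties remove the later SNP) on dosage correlations, and a
PCA screen flags samples whose nearest taxon centroid (leave-one-out for
their own) is not their assigned taxon by a margin factor of 1.5 on the top
5 axes. The screen codifies what is usually done by eye; margin and axis
count are tunable. Intensities are never filtered: the intensity route uses
every array SNP by design.

**\(F_{ST}\).** For each taxon pair, per-locus variance components of the
two-population diploid moment estimator are combined ratio-of-sums across
loci, \(\theta = \sum_l a_l / \sum_l (a_l + b_l + c_l)\) — the "weighted
average" estimator. Loci monomorphic for the same allele in both taxa are
0/0 and excluded; loci need at least two non-missing diploids per taxon.
Negative \(\theta\) is retained; before tree building the off-diagonal is
shifted up by the minimum only if any entry is negative (logged). A
fixed difference gives \(\theta = 1\); identical all-heterozygote samples
give \(\theta = 0\).

**Neighbor joining** is implemented with the standard Q-criterion. For
reproducibility across platforms the input is label-sorted, Q-ties are
broken by the lexicographically smallest label pair (clusters keyed by their
smallest leaf), and negative branch lengths are clamped to zero (topology
untouched, deficit reported). NJ on an exactly additive matrix returns the
generating tree and branch lengths. Rooting places the root at the midpoint
of the outgroup's pendant edge, which leaves the bipartition set unchanged.

## The intensity route

Seven summary statistics of the channel pair are supported: X, Y, X+Y,
X/(X+Y), ln X/(X+Y), ln Y/(X+Y) and ln(X/Y); the default reported statistic
is ln(X/Y). The log statistics rely on the strictly positive intensity
floor rather than pseudocounts, so the seven functions are exactly as
written. A species' "quantitative genotype" is the per-SNP median over its
samples (even counts: mean of the central pair), computed over **all** array
SNPs and all samples with intensities, including those whose call is
missing -- missing calls are where the off-target signal lives. Distances
are plain Euclidean distances between species profiles.

Tree comparisons use the bipartition (Penny--Hendy / Robinson--Foulds)
distance: the symmetric difference of the two trees' non-trivial splits,
which for binary trees equals twice the number of internal branches whose
bipartitions differ. Matrix comparisons use a Mantel test (Pearson r of
lower triangles, simultaneous row/column permutations, one-sided add-one
p-value, default 10000 permutations) and classical MDS (double-centering +
eigendecomposition, axes signed so the largest-magnitude coordinate is
positive).

The "systematic elevation" of focal-involving intensity distances is
operationalized as a rank statistic: both matrices' off-diagonals are
rank-transformed to [0, 1] and the statistic is the mean rank difference
(intensity minus genotype) over focal-involving pairs. Rank transformation
makes the statistic scale-free across the two distance types; identical
matrices give exactly 0.

## The synthetic ascertained array

The generator produces datasets with the statistical structure the analysis
assumes, so every stage is testable against a known truth.

* **Species tree**: a user newick (branch lengths required) or a pure-birth
  tree rescaled to unit maximum root-to-tip depth, with branch lengths
  floored at 0.05. Time is measured in drift units: along a branch of
  length \(t\) the fixation index is \(F = 1 - e^{-t}\). Unit depth puts
  typical between-taxon fixation indices in the 0.4--0.9 range --
  well-separated species with near-complete allele sorting in the most
  diverged taxa. The floor encodes that species-level radiations do not
  contain effectively zero-length internal branches.
* **Allele frequencies**: the root frequency is Uniform(0.05, 0.95) per SNP;
  children follow the Balding--Nichols law
  \(p' \sim \mathrm{Beta}(p(1-F)/F, (1-p)(1-F)/F)\), which has mean \(p\),
  variance \(p(1-p)F\), and is the standard bounded drift model in the
  ascertainment literature. Frequencies within \(10^{-4}\) of the bounds are
  absorbed; zero-length branches copy the parent exactly.
* **Ascertainment**: a discovery panel (default 11 focal individuals plus
  one each from six other taxa -- 17 in all) is *sampled* from the true
  frequencies, and a candidate SNP is retained iff its sampled panel MAF is
  at least 0.10. Using sampled panel genotypes rather than true frequencies
  makes panel size and composition matter, as in real SNP discovery.
* **Genotypes**: Binomial(2, p) dosages per sample, 1% missing completely
  at random on top of quality-based masking (below).
* **Intensities**: probe affinity decays with tree path distance \(d_s\)
  from the focal taxon, \(\alpha = e^{-\lambda d_s}\) (default
  \(\lambda = 0.5\)). OTVs arise as probe-site mutations on the branches of
  the path focal \(\to\) taxon (per SNP, per branch, probability
  \(1 - e^{-\mu t}\), default \(\mu = 0.3\)), so a taxon carries an OTV with
  marginal probability \(1 - e^{-\mu d_s}\) *and* sister taxa share OTVs --
  real probe-site mutations are inherited, and this sharing is what makes
  the off-target signal phylogenetically informative rather than pure
  noise. An OTV multiplies affinity by \(1 - \delta\) (default
  \(\delta = 0.5\)). Channels are
  \(X = \max(\varepsilon_0, \alpha S (2-g)/2 + b + N(0, \sigma^2))\) and
  symmetrically for Y, with signal \(S = 1\), background \(b = 0.05\),
  channel noise \(\sigma = 0.04\) and floor \(\varepsilon_0 = 0.02\) --
  roughly a 20:1 full-scale signal-to-noise ratio with a small shared
  background, typical of normalized two-channel array output.
* **Quality scores**: the GenCall-like per-call score is
  \(e^{-d_{\min}/\tau}\), \(\tau = \sigma + \varepsilon_0\), where
  \(d_{\min}\) is the distance to the nearest noise-free cluster centroid at
  the *taxon-level* affinity. Excluding the SNP-specific OTV penalty from
  the centroids reflects cluster retraining: a whole taxon's systematic
  decay is absorbed, but OTV-shifted samples fall off-cluster and score low,
  so their calls are masked by the GenCall < 0.2 filter -- this is the
  mechanism by which off-target variation erodes the genotype route for
  diverged taxa. The GenTrain-like per-SNP score is
  \(\mathrm{gap}/(\mathrm{gap} + 4\sigma)\) with gap the smallest distance
  between the empirical dosage-class centroids (1 when fewer than two
  classes are observed).

**What the generator does not emulate**: linkage between SNPs (LD pruning is
exercised on constructed duplicated-SNP fixtures), coalescent gene-tree
heterogeneity, hybridization/introgression, allele-specific probe dropout,
batch or plate effects, and the array's internal normalization. Passing
tests therefore demonstrate correctness of the estimators and the direction
of ascertainment effects under a clean drift model, not performance on any
real dataset.

A model-structure consequence worth knowing: under the channel formulas the
noise-free sum \(X + Y = \alpha S + 2b\) is independent of the genotype, so
the X+Y summary statistic carries only affinity/OTV signal. Its distance
matrix remains strongly Mantel-correlated with the other six (affinity decay
is shared structure), but its NJ tree can sit a few bipartitions away from
theirs, whereas the six genotype-informative statistics agree to within one
differing internal branch on default simulations.

## The replicate experiment

`run_replicate_experiment()` repeats simulate → both routes → compare
against truth, with per-replicate seeds derived from one master seed (all
stage seeds come from a single `derive_seeds()` stream, so any stage can be
re-run in isolation). Per replicate it records each route's bipartition
distance to the true tree (after rooting everything on the designated
outgroup, the leaf farthest from the focal taxon by default) and whether the
focal taxon's true sister group is recovered; the summary gives per-route
means and a paired sign test (ties dropped, exact binomial).

Default problem sizes -- 12 taxa, 20 samples per taxon, 2000 candidate SNPs
(roughly half survive ascertainment), 50 replicates -- keep a full
experiment around a minute of CPU while leaving the per-replicate trees
non-trivial (18 possible internal-branch mismatches).

Under these defaults the bias diagnostics are unambiguous (intermediate-MAF
excess in the focal taxon, shared-monomorphic deficit and compressed
\(F_{ST}\) band for focal pairs, positive intensity elevation that vanishes
when \(\lambda = \mu = 0\)), while *both* routes recover the true topology
in most replicates; the intensity route is typically better in the mean, but
replicates where the two routes differ are few, so the paired sign test has
limited power at this drift depth. A harsher regime -- deeper divergence
with near-complete sorting in all non-focal taxa, or the highly unequal
sample sizes of a real germplasm collection -- widens the gap; the package
reports whatever the configured conditions produce.

## Numerical choices and degenerate inputs

* Distance matrices must be symmetric within 1e-9 on write (1e-5 on read)
  and are symmetrized by averaging; PHYLIP labels are truncated to 10
  characters with deterministic disambiguation.
* `neighbor_joining()` requires \(n \ge 3\) finite entries; NaN anywhere is
  a hard error. Q-ties are exact floating-point ties, resolved by label.
* Monomorphic SNPs have undefined LD \(r^2\) and are treated as
  uncorrelated; all-missing SNPs have no definable MAF and are removed by
  the MAF rule.
* `classical_mds()` truncates (with a warning) when fewer than `k` positive
  eigenvalues exist and tolerates mildly non-Euclidean input.
* Mantel tests refuse constant matrices (the correlation is undefined) and
  fewer than 4 labels.
* Taxa with one sample cannot be screened by the leave-one-out curation
  rule; they are reported with a warning and never flagged.
* All RNG flows through explicit seeds; `withr::with_seed()` keeps the
  global RNG state untouched.

## Worked example

```{r example, eval = FALSE}
library(arrayphylo)

sim <- simulate_array_dataset(sim_config(seed = 7))
filt <- apply_genotype_filters(sim$genotypes, sim$manifest)
stats <- species_allele_stats(filt$genotypes, sim$species_map)
fst <- pairwise_fst_matrix(stats)
gtree <- root_with_outgroup(neighbor_joining(shift_nonnegative(fst)),
                            sim$truth$outgroup)

profiles <- species_median_profiles(sim$intensities, sim$species_map, "LN_XY")
itree <- root_with_outgroup(neighbor_joining(euclidean_species_distance(profiles)),
                            sim$truth$outgroup)

truth <- root_with_outgroup(sim$truth$tree, sim$truth$outgroup)
tree_topology_distance(gtree, truth)
tree_topology_distance(itree, truth)
```
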