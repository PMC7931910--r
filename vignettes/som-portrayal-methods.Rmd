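---
title: "SOM transcriptome portrayal: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SOM transcriptome portrayal: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(somportrait)
```

This vignette is the package's own account of the methods it implements:
the models and their assumptions, the parameters that matter, what the
synthetic cohort does and does not emulate, and the design decisions
taken where the method left genuine freedom.

## The portrayal model

The pipeline treats each **gene** as a data point in sample space. Given
a centered genes × samples log2-expression matrix, a batch
self-organizing map with `K = grid_rows × grid_cols` units is trained on
the gene profiles. Each unit's codebook vector is a **metagene**: the
profile, across samples, of the micro-cluster of co-expressed genes whose
best-matching unit (BMU) it is. Because the grid is two-dimensional and
the neighborhood function is spatially smooth, similar metagenes occupy
neighboring units, so one sample's column through the codebook — its
**portrait** — is a coherent image in which co-expressed gene clusters
appear as contiguous red (over-expressed) or blue (under-expressed)
areas.

Assumptions worth stating explicitly:

- Expression is on log scale, quantile-normalized across samples, and
  every gene is mean-centered. Portraits therefore show expression
  *relative to the cohort mean*, and a "spot" is a deviation, not an
  absolute abundance.
- The Euclidean metric in sample space drives both BMU assignment and
  the distance ("U-matrix") criteria downstream; genes with large
  absolute deviations dominate.
- The map is planar, not toroidal: corners are meaningful, and opposing
  expression states tend to occupy opposite map regions.

### Training schedule

Training is **batch** SOM: per epoch, all genes are assigned to their
nearest codebook vector, then every unit is recomputed as the Gaussian
neighborhood-weighted mean of the assigned genes. Batch updates make the
result independent of gene order and deterministic given the
initialization; ties in BMU assignment break toward the lowest unit
index.

- *Initialization*: the codebook spans the plane of the first two
  principal components of the gene cloud (computed from the sample-space
  cross-product matrix with a deterministic sign convention), falling
  back to a seeded random sample of gene rows for degenerate covariance.
  PCA initialization fixes the map's global orientation so repeated runs
  do not flip topology.
- *Radius schedule*: the Gaussian neighborhood radius decays linearly
  from `max(grid_rows, grid_cols)/2` to **0.5** over 20 epochs. The
  final value matters: ending at radius 1 leaves ≈ 0.6 weight on
  immediate neighbors and smears adjacent co-expression domains into one
  another, flattening exactly the metagene-distance ridges that spot
  segmentation relies on; 0.5 ends training in the near-local regime
  while keeping earlier epochs' topological ordering.
- *Empty units* keep their previous codebook vector, preserving the
  dense-map portrayal style; such units act as smooth interpolation
  between occupied domains.

`quantization_error()` (mean gene-to-BMU distance) is tracked per epoch;
on the package's synthetic data it does not end above its first-epoch
value, the usual sanity check that the schedule anneals rather than
oscillates.

Grid size is a free parameter. Population-scale analyses use grids of
order 100 × 100 (about half as many units as genes); the package's test
and example scale is 16 × 16 for 2,000 genes, which keeps a full
analysis around two seconds while leaving each planted module a handful
of units.

## Spot segmentation

Spots are the analysis' unit of co-expression: connected grid regions of
strong over-expression together with their member genes. Detection
composes three criteria:

1. **Candidate units** — the per-unit 98th percentile of codebook values
   across samples (`overexpression_summary()`) summarizes how strongly a
   metagene is *ever* over-expressed. By default the summary map is
   split into a low and a high regime by two-class 1-D k-means and the
   high regime is kept. A fixed rank threshold (`top_quantile`, e.g.
   0.98) is also available; it presumes a map much larger than the
   structure it segments (on a 100 × 100 grid the top 2% is 200 units,
   on 16 × 16 it is five), which is why the scale-free split is the
   default.
2. **Gene occupancy** — candidate units must carry at least one BMU
   gene. Geneless units are interpolation between domains; including
   them lets smooth codebook gradients bridge two distinct spots.
3. **Halo gating** — the classic criterion localizes boundaries at
   metagenes of maximal distance to their neighbors, the closed
   "halo" lines around spots. The package applies it to *adjacencies*:
   two neighboring candidate units connect only if their codebook
   distance lies at or below the `ridge_quantile` (default 0.85) of all
   neighbor-pair distances on the map. Gating edges rather than deleting
   whole units matters at small grid sizes, where a spot may be only
   two or three units wide and removing its rim would destroy it.

Connected components (8-connectivity) of the gated candidate graph are
then filtered by `min_units` (default scales with map area,
`max(1, K/200)`) and `min_genes` (default 5 — a couple of stray genes is
not a co-expression module), capped at `max_spots` (25) and lettered
`A`, `B`, … by decreasing gene count. Letters are size-ranked, not
position-ranked: spot identities across different maps are established
by gene-set overlap (`match_modules()`), never by label.

The defaults sit on a plateau, not a knife edge: on the default
synthetic cohort the recovered module count and gene-set Jaccard are
unchanged for `ridge_quantile` anywhere in 0.75–0.85.

## Stratification

A sample's **cPAT** is the set of spots whose expression, z-scored
across samples within the spot, exceeds `z_threshold = 1`. The z-score
criterion is deliberately relative: a spot "counts" for a sample when
that sample is in the spot's upper expression tail, regardless of the
spot's absolute level. Patterns observed at least `min_count = 5` times
are *major*.

The tentative number of types is estimated from the major cPATs: each
pattern's centroid portrait is computed, centroids are clustered by
average-linkage hierarchical clustering on Euclidean distance, and the
tree is cut at the largest merge-height gap (bounded to `[2, n_major]`).
K-means (25 seeded restarts) on the full metagene vectors then assigns
types, and a second K-means within each type assigns `n_subtypes = 3`
subtypes. Clustering operates in full portrait space rather than on
spot profiles so that information outside detected spots still
contributes.

Cluster labels from K-means are arbitrary, so a deterministic relabeling
makes them reproducible: types are ranked by their centroids' mean
expression of the reference spot (largest spot by default; any spot or
an external anchor can be supplied), the lowest becoming type `1`; with
three clusters the pair of centroids with the most negative mutual
correlation are the extremes (`1`, `2`) and the remaining,
correlation-intermediate cluster is `M`.

Stratifications are validated by repeated stratified holdout (default
10 rounds, 30% held out): a linear classifier is trained on the
training split's metagene vectors and the held-out samples are
reclassified. The default classifier is a linear support-vector machine
(`e1071::svm`, cost 1), the classifier family used for this purpose in
cohort portrayal studies; a rank-reduced linear discriminant
(`method = "lda"`, LDA on the leading principal components, which keeps
the pooled covariance well-conditioned when features outnumber samples)
is provided as an alternative with the same interface.

## Function mining

Spot gene lists are tested for gene-set over-representation with the
exact hypergeometric right tail (`P(X ≥ overlap)`), identical to a
one-sided Fisher test on the 2 × 2 membership table; Benjamini–Hochberg
FDR is reported across all (spot, set) cells.

The sample-wise **GSZ** score is

```
GSZ = sqrt(n_S) * (mean_S - mean_U) / sqrt(w * var_S + (1 - w) * var_U)
```

with set mean/variance `mean_S`, `var_S`, universe mean/variance
`mean_U`, `var_U`, and pooling weight `w = 0.5`. Design choices here:
population (1/n) variances, so the two-point toy cases used in the tests
evaluate exactly; the pooling weight is exposed because the underlying
principle — "mean expression of the set normalized by its variance" —
does not pin down a unique formula; a singleton set's undefined variance
term falls back to the universe variance; a zero denominator returns 0.
Consequences of the form: GSZ is invariant under adding a constant to a
sample's expression and under positive rescaling (both numerator and
denominator scale by |c|), and a set equal to its universe scores
exactly 0.

## Phenotype portrayal

Phenotype-to-metagene **correlation maps** compute, per grid unit, the
correlation over samples between the phenotype and the metagene profile:
Pearson for continuous features, point-biserial for binary ones —
computed as Pearson on the 0/1 coding, which is the same number by
identity (the package tests this to machine precision) — and one
one-vs-rest binary map per level for categorical features. Missing
phenotype values are dropped pairwise and the number used is reported;
zero-variance metagenes correlate 0 by convention, zero-variance
features are an error.

Type-phenotype association uses the same right-tailed hypergeometric
test on (in type) × (has level) tables with BH-FDR across cells;
standardized multiple regression (`spot_regression()`) z-scores both the
spot profile and all predictors so coefficients are comparable effect
sizes, dropping collinear columns via QR with a warning. LOESS trends
(`loess_trend()`) are tricube-weighted local *linear* fits (degree 1,
span 0.5 by default — degree 1 avoids boundary curvature artifacts at
the age extremes where cohort data thin out), evaluated on 100 evenly
spaced covariate points, optionally per group; spans too small to hold
a local neighborhood are widened with a warning.

## The synthetic cohort: what it emulates, and what it does not

`generate_cohort()` plants known structure so that every downstream
stage has ground truth. The generative model is deliberately simple:

```
e[g, s] = a[s, module(g)] + eps,   eps ~ N(0, noise_sd^2)
a[s, m] = base[type(s), m] + boost(subtype(s), m) + sum_p beta[p, m] * phen[s, p]
```

with binary gene loadings (a gene is in exactly one module or in the
background) and `noise_sd = 1` log2 unit. The default geometry, chosen
once to realize the structure a blood-cohort portrayal study reports —
about a dozen co-expression modules; two strongly anti-correlated
extreme types plus an intermediate one; three subtypes per type, each a
distinct combination of over-expressed modules; one type-independent
module active in ~10% of samples, after the interferon-response
signature such studies observe — is:

- 2,000 genes × 300 samples; 13 modules × 40 genes (74% background);
- modules 1–6 are the type-1 block (base +3 in type 1, −3 in type 2),
  modules 7–12 the type-2 block (mirrored); the anti-correlation of the
  extreme types' portraits follows directly;
- extreme-type subtypes boost (+5) a cyclic window of three own-block
  modules with stride 2 ({1,2,3}, {3,4,5}, {5,6,1}), so the windows
  cover the block and every module has a unique subtype signature —
  without that uniqueness two modules would have identical activation
  profiles and could not be separated by any method, making the planted
  "13 modules" ill-posed;
- the intermediate type M owns no block but carries a moderate (+3) base
  on the cross-pair module pool {2,4,6,8,10,12} and its subtypes boost
  (+3.5) disjoint cross-block pairs {2,8}, {4,10}, {6,12}. The base
  signature places M off the type-1/type-2 axis. This is not cosmetic:
  if M sits exactly midway between the extremes, the distance from M to
  either extreme is half the extreme-to-extreme distance, the top merge
  of any centroid dendrogram dominates every other gap, and no cut of
  the tree can return three groups — the planted "three types" would be
  structurally unrecoverable by the estimation method. An intermediate
  stratum with some expression character of its own is also what cohort
  studies describe;
- module 13 activates (+5) in a random 10% of samples of all types;
- phenotypes: age ~ U(40, 80) years; sex ~ Bernoulli(0.5); BMI ~
  N(27, 4) kg/m² with a mild age trend; a binary disease flag drawn by
  a logistic threshold on age with a higher rate in type-1 samples
  (emulating a disease–type association strong enough to be detected at
  the default cohort size). Default couplings feed age, sex, BMI and the
  flag into one module each with slopes in log2 units per phenotype
  unit.

What the generator does **not** emulate: probe- or array-level
artifacts, batch effects, missing values, correlated background genes
(background is i.i.d. noise, whereas in real data every gene carries
some co-expression structure), realistic blood-cell composition, or the
long-tailed module size distribution of real spot catalogs. Passing the
package's recovery tests therefore demonstrates that the pipeline's
machinery — map training, segmentation, pattern logic, clustering,
validation — is correct and internally consistent at the planted effect
sizes; it does not certify performance on real cohort data, where
effect sizes are smaller, modules overlap, and background structure
blurs the halo boundaries.

## Numerical conventions and degenerate inputs

- Quantile normalization resolves ties by assigning tied values the mean
  of the order-statistic means they span; centering uses the mean (not
  the median).
- BMU ties break to the lowest unit index; K-means uses 25 restarts with
  a set seed; all stage functions thread a single integer seed.
- Degenerate cases have defined, tested behavior: empty candidate sets
  give zero spots (not an error); zero-variance spot profiles are never
  over-expressed; a single major cPAT yields k = 1 with a warning, as
  does an all-identical centroid tree (k forced to the lower bound);
  holdout rounds missing a class are skipped with a warning; overlap 0
  gives Fisher p = 1 exactly.
- Problem sizes used throughout tests and the acceptance script —
  2,000 × 300 cohorts on 16 × 16 maps, five generator seeds — are the
  package's default desk scale; the full population scale (19,049 genes,
  thousands of samples, 100 × 100 maps) remains a configuration choice.

## Known limitations

- Spot letters are not comparable across maps; always match spots by
  gene content.
- The largest-gap rule for the type count inspects one dendrogram and
  can be unstable when group separations are comparable; the estimate is
  labelled *tentative* and `cluster_types()` accepts any k.
- The GSZ normalization is one member of the family consistent with its
  verbal definition; the pooling weight is a parameter, and scores
  should be compared only within one choice of weight.
- The SOM schedule is a declared, reproducible substitute for the
  historical implementations' (undocumented) schedules; correctness is
  assessed by topology-recovery properties, not bit-agreement with any
  particular legacy tool.
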