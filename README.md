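# somportrait

Self-organizing map (SOM) portrayal and stratification of transcriptome
cohorts.

Population-scale blood transcriptomics produces a genes × samples
expression matrix too large to reason about gene by gene. The SOM
portrayal approach compresses the *N* gene expression profiles into
*K* = `grid_rows × grid_cols` **metagenes** — codebook vectors arranged on
a two-dimensional grid, each representing a micro-cluster of co-expressed
genes — so that every sample can be rendered as a colored **portrait** of
its transcriptome on that grid. Downstream of the map, the package:

- segments the metagene landscape into co-expression **spot modules**
  (connected high-expression grid regions bounded by the "halo" lines of
  large metagene-to-metagene distance), each carrying a gene list and a
  per-sample expression profile;
- assigns each sample a **combinatorial pattern type (cPAT)** — the set
  of spots over-expressed in it (spot *z*-score > 1 across samples) —
  estimates the number of strata from the cPAT centroid dendrogram, and
  K-means-clusters the portraits into transcriptome **types** (labelled
  `1`, `M`, `2`) and nested **subtypes** (`1.1` … `2.3`), with
  holdout/linear-classifier validation of the stratification;
- performs **function mining**: right-tailed Fisher's exact
  (hypergeometric) over-representation of gene sets in spot gene lists,
  the sample-wise gene-set *z*-score
  `GSZ = √n_S · (ē_S − ē_U) / √(w·var_S + (1−w)·var_U)`, and gene-set
  location maps on the grid;
- maps **phenotypes onto the metagene landscape**: Pearson (continuous)
  and point-biserial (binary) correlation portraits per grid unit,
  one-tailed Fisher enrichment of categorical phenotypes in types,
  standardized multiple regression of spot expression on phenotype
  designs, and LOESS trend curves.

Because population cohort data of this kind are typically
access-restricted, the package ships a first-class synthetic-cohort
generator (`generate_cohort()`) with planted ground truth — 13 gene
modules whose activations define three sample types (two anti-correlated
extremes and an intermediate type) split into nine subtypes, plus
age/sex/BMI/disease covariates coupled to module activations — so every
stage of the pipeline can be validated end to end against known
structure.

## Worked example

```r
library(somportrait)

cohort <- generate_cohort(cohort_config(seed = 1))
#> Synthetic cohort: 2000 genes x 300 samples; 13 planted modules; 3 types / 9 subtypes

x     <- preprocess_expression(cohort$expression)   # quantile normalize + center genes
model <- train_som(x, grid_rows = 16, grid_cols = 16, seed = 1)
#> SOM model: 16 x 16 grid ( 256 metagenes ), 2000 genes, 300 samples
#>   epochs: 20  final quantization error: 17.37

spots <- detect_spots(model)
spots[, c("spot_id", "n_units", "n_genes")]
#> # A tibble: 13 x 3   (spots A..M, 40 genes each)

cpats <- assign_cpats(spots)
enumerate_cpats(cpats)
#> # A tibble: 18 x 3
#>   cpat      n major
#> 1 B+C+D    31 TRUE
#> 2 I+J+M    31 TRUE
#> 3 A+B+F    30 TRUE
#> ...

k <- estimate_type_count(model, cpats)       # k = 3
assignment <- cluster_types(model, k = as.integer(k), spots = spots, seed = 1)
glance(assignment)
#>   n_samples n_types n_subtypes
#> 1       300       3          9

validate_types(model, assignment, seed = 1)  # holdout misclassification: 0

match_modules(spots, cohort$truth)           # median Jaccard vs planted modules: 1
```

The 13 detected spots recover the 13 planted modules exactly (median
gene-set Jaccard 1.0); the three recovered types match the planted type
labels with adjusted Rand index 1.0, and repeated 70/30 holdout
reclassification with a linear SVM misclassifies 0% of samples.

Portraits and maps plot directly:

```r
autoplot(portrait(model, "S0001"))          # one sample's expression portrait
autoplot(spots)                             # summary map with spot letters
autoplot(correlation_map(model, cohort$phenotypes, "age"))
```

`run_pipeline(pipeline_config(...))` chains all stages, writes plain-text
artifacts (spot gene lists, profiles, type assignments, enrichment
tables, phenotype overview, JSON run summary) and is deterministic given
its seed.

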