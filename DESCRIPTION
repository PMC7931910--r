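Package: somportrait
Title: Self-Organizing Map Portrayal and Stratification of Transcriptome Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains self-organizing maps of gene expression profiles into
    metagene grids, renders per-sample expression portraits, segments
    co-expression "spot" modules from the metagene landscape, stratifies
    samples into combinatorial pattern types, transcriptome types and
    subtypes, performs gene-set enrichment (Fisher's exact test and a
    sample-wise gene-set z-score), and maps phenotype-to-metagene
    correlations. Ships a synthetic-cohort generator with planted module,
    type and phenotype structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    limma,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
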