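# Shared fixtures, built once per test run.

# Default synthetic cohort analysed end-to-end (the study conditions:
# 2,000 genes x 300 samples, 16 x 16 map).
default_analysis <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cohort <- generate_cohort(cohort_config(seed = 1))
      x <- preprocess_expression(cohort$expression)
      model <- train_som(x, 16, 16, epochs = 20, seed = 1)
      spots <- detect_spots(model)
      cache <<- list(cohort = cohort, x = x, model = model, spots = spots,
                     matching = match_modules(spots, cohort$truth),
                     cpats = assign_cpats(spots))
    }
    cache
  }
})

# The same analysis across five generator seeds (spot counts, matching,
# type-count estimate, clustering agreement); shared by the stratification
# and acceptance tests.
multi_seed_runs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- lapply(1:5, function(seed) {
        cohort <- generate_cohort(cohort_config(seed = seed))
        x <- preprocess_expression(cohort$expression)
        model <- train_som(x, 16, 16, epochs = 20, seed = seed)
        spots <- detect_spots(model)
        mm <- match_modules(spots, cohort$truth)
        cpats <- assign_cpats(spots)
        k <- as.integer(suppressWarnings(estimate_type_count(model, cpats)))
        asg <- cluster_types(model, k = k, spots = spots, seed = seed)
        truth <- cohort$truth$sample_type
        list(seed = seed, model = model, spots = spots,
             n_spots = nrow(spots), matching = mm, k = k,
             assignment = asg, truth = truth,
             ari_type = adjusted_rand_index(asg$type, truth$type),
             ari_subtype = adjusted_rand_index(asg$subtype, truth$subtype))
      })
    }
    cache
  }
})

# Hand-built SOM model (no training) for construction-based tests.
make_model <- function(codebook, grid_rows, grid_cols, gene_bmu = NULL,
                       sample_ids = NULL) {
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("S%d", seq_len(ncol(codebook)))
  }
  colnames(codebook) <- sample_ids
  if (is.null(gene_bmu)) {
    gene_bmu <- stats::setNames(seq_len(nrow(codebook)),
                                sprintf("g%d", seq_len(nrow(codebook))))
  }
  structure(list(codebook = codebook, grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols), gene_bmu = gene_bmu,
                 sample_ids = sample_ids,
                 meta = list(epochs = 0L, radius_start = NA, radius_end = NA,
                             seed = NA_integer_, qe_history = numeric(0))),
            class = "som_model")
}

# Minimal spot_set carrying only profiles (for cPAT logic tests).
make_spot_set <- function(profiles, units = NULL, genes = NULL) {
  n <- nrow(profiles)
  if (is.null(units)) units <- as.list(seq_len(n))
  if (is.null(genes)) genes <- lapply(seq_len(n), function(i) sprintf("g%d", i))
  out <- tibble::tibble(spot_id = rownames(profiles),
                        n_units = lengths(units),
                        n_genes = lengths(genes),
                        units = units, genes = genes)
  attr(out, "profiles") <- profiles
  attr(out, "grid_rows") <- 1L
  attr(out, "grid_cols") <- max(unlist(units))
  class(out) <- c("spot_set", class(out))
  out
}
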