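#' Read / write a genes x samples expression matrix as TSV
#'
#' Plain-text interchange: first column `gene_id`, remaining columns one
#' per sample. Duplicate gene or sample identifiers are rejected.
#'
#' @param path File path.
#' @return `read_expression()`: numeric matrix with gene rownames and
#'   sample colnames.
#' @export
read_expression <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 2 || names(df)[1] != "gene_id") {
    stop("malformed expression file '", path,
         "': expected a gene_id column followed by sample columns",
         call. = FALSE)
  }
  ids <- as.character(df$gene_id)
  if (anyDuplicated(ids)) {
    stop("duplicate gene ids in '", path, "': ",
         paste(utils::head(ids[duplicated(ids)], 3), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(names(df)[-1])) {
    stop("duplicate sample ids in '", path, "'", call. = FALSE)
  }
  bad <- which(!vapply(df[-1], is.numeric, TRUE))
  if (length(bad)) {
    stop("non-numeric expression column(s) in '", path, "': ",
         paste(names(df[-1])[bad], collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(df[-1])
  rownames(m) <- ids
  m
}

#' @rdname read_expression
#' @param x Numeric matrix, genes x samples, with dimnames.
#' @export
write_expression <- function(x, path) {
  x <- as.matrix(x)
  df <- tibble::as_tibble(x, rownames = "gene_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read / write a phenotype table as CSV
#'
#' First column `sample_id`; any number of feature columns (continuous,
#' 0/1 binary, or categorical strings). Missing cells are allowed; their
#' count is reported and stored in `attr(, "n_missing")`.
#'
#' @param path File path.
#' @return `read_phenotypes()`: tibble.
#' @export
read_phenotypes <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 2 || names(df)[1] != "sample_id") {
    stop("malformed phenotype file '", path,
         "': expected a sample_id column followed by feature columns",
         call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample ids in '", path, "'", call. = FALSE)
  }
  n_missing <- sum(is.na(df[-1]))
  if (n_missing > 0) {
    message(n_missing, " missing phenotype value(s) in '", path, "'")
  }
  attr(df, "n_missing") <- n_missing
  df
}

#' @rdname read_phenotypes
#' @param x Phenotype tibble with a `sample_id` column.
#' @export
write_phenotypes <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene ids. Lines with fewer than three fields are rejected with
#' their line numbers.
#'
#' @param path File path.
#' @return `read_gmt()`: named list of character gene-id vectors, with the
#'   descriptions in `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad)) {
    stop("malformed GMT '", path, "': fewer than 3 fields at line(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(names(sets))) {
    stop("duplicate set names in '", path, "'", call. = FALSE)
  }
  attr(sets, "description") <- vapply(fields, `[[`, "", 2)
  sets
}

#' @rdname read_gmt
#' @param sets Named list of gene-id vectors.
#' @param description Optional per-set description strings.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  if (is.null(description)) description <- rep("na", length(sets))
  lines <- mapply(function(nm, de, genes) {
    paste(c(nm, de, genes), collapse = "\t")
  }, names(sets), description, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Write a synthetic cohort to plain-text files
#'
#' Expression as TSV, phenotypes as CSV, ground truth as JSON and the
#' generating configuration as YAML.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "som_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  write_phenotypes(cohort$phenotypes, file.path(dir, "phenotypes.csv"))
  truth <- list(
    gene_module = cohort$truth$gene_module,
    sample_type = cohort$truth$sample_type
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA)
  cfg <- cohort$truth$config
  cfg_out <- cfg[setdiff(names(cfg), c("activation_matrix",
                                       "phenotype_effects"))]
  cfg_out$activation_matrix <- apply(cfg$activation_matrix, 1, identity,
                                     simplify = FALSE)
  cfg_out$phenotype_effects <- as.list(cfg$phenotype_effects)
  yaml::write_yaml(cfg_out, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Configure the end-to-end portrayal pipeline
#'
#' @param expression Expression matrix (genes x samples, log2, not yet
#'   centered) or path to a TSV readable by [read_expression()].
#' @param phenotypes Optional phenotype tibble or CSV path.
#' @param gene_sets Optional named list of gene sets or GMT path.
#' @param grid_rows,grid_cols SOM grid (default 16 x 16).
#' @param epochs Training epochs (default 20).
#' @param top_quantile,ridge_quantile,min_units,max_spots Spot-detection
#'   settings, see [detect_spots()].
#' @param z_threshold cPAT over-expression criterion, see [assign_cpats()].
#' @param min_count Major-cPAT count threshold, see [enumerate_cpats()].
#' @param k Number of types; `NULL` (default) estimates it from the major
#'   cPATs via [estimate_type_count()].
#' @param n_subtypes Subtypes per type (default 3).
#' @param seed Integer seed driving every stochastic stage.
#' @param out_dir Optional directory; when given, every stage artifact and
#'   a JSON run summary are written there.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(expression, phenotypes = NULL, gene_sets = NULL,
                            grid_rows = 16, grid_cols = 16, epochs = 20,
                            top_quantile = NULL, ridge_quantile = 0.90,
                            min_units = 4, max_spots = 25,
                            z_threshold = 1.0, min_count = 5,
                            k = NULL, n_subtypes = 3,
                            seed = 1L, out_dir = NULL) {
  check_range <- function(v, lo, hi, nm) {
    if (!is.null(v) && (v < lo || v > hi)) {
      stop("config error: ", nm, " must be in [", lo, ", ", hi, "]",
           call. = FALSE)
    }
  }
  check_range(top_quantile, 0.5, 0.999, "top_quantile")
  check_range(ridge_quantile, 0.5, 1, "ridge_quantile")
  check_range(z_threshold, 0, 5, "z_threshold")
  if (is.null(seed)) stop("config error: seed is mandatory", call. = FALSE)
  structure(as.list(environment())[c(
    "expression", "phenotypes", "gene_sets", "grid_rows", "grid_cols",
    "epochs", "top_quantile", "ridge_quantile", "min_units", "max_spots",
    "z_threshold", "min_count", "k", "n_subtypes", "seed", "out_dir"
  )], class = "pipeline_config")
}

#' Run the full portrayal workflow
#'
#' Executes preprocess, map training, spot segmentation, cPAT/type/subtype
#' stratification, optional gene-set enrichment and optional phenotype
#' portrayal in order, logging one line per stage. Deterministic given the
#' config seed. With `out_dir` set, stage artifacts (spot gene lists, spot
#' profiles, type assignment, enrichment tables, phenotype overview,
#' correlation matrix) and a JSON summary of counts and parameters are
#' written as plain text.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `som_pipeline`: list with `model`, `spots`,
#'   `cpats`, `assignment`, `enrichment`, `phenotype_overview`,
#'   `validation` and `summary`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  x <- stage("read", {
    if (is.character(config$expression)) read_expression(config$expression)
    else as.matrix(config$expression)
  })
  phen <- stage("read", {
    if (is.character(config$phenotypes)) read_phenotypes(config$phenotypes)
    else config$phenotypes
  })
  gene_sets <- stage("read", {
    if (is.character(config$gene_sets)) read_gmt(config$gene_sets)
    else config$gene_sets
  })

  message("[preprocess] ", nrow(x), " genes x ", ncol(x), " samples")
  x <- stage("preprocess", preprocess_expression(x))

  message("[train] ", config$grid_rows, "x", config$grid_cols,
          " grid, ", config$epochs, " epochs")
  model <- stage("train", train_som(
    x, grid_rows = config$grid_rows, grid_cols = config$grid_cols,
    epochs = config$epochs, seed = config$seed))

  spots <- stage("spots", detect_spots(
    model, top_quantile = config$top_quantile,
    ridge_quantile = config$ridge_quantile,
    min_units = config$min_units, max_spots = config$max_spots))
  message("[spots] ", nrow(spots), " spots, ", sum(spots$n_genes),
          " member genes")

  strat <- stage("stratify", {
    cpats <- assign_cpats(spots, z_threshold = config$z_threshold)
    k <- config$k
    if (is.null(k)) {
      k <- as.integer(estimate_type_count(model, cpats,
                                          min_count = config$min_count))
    }
    assignment <- cluster_types(model, k = k,
                                n_subtypes = config$n_subtypes,
                                spots = spots, seed = config$seed)
    validation <- if (length(unique(assignment$type)) >= 2) {
      validate_types(model, assignment, seed = config$seed)
    } else {
      NA_real_
    }
    list(cpats = cpats, k = k, assignment = assignment,
         validation = validation)
  })
  message("[stratify] ", strat$k, " types, ",
          length(unique(strat$assignment$subtype)), " subtypes, ",
          length(unique(strat$cpats$cpat)), " cPATs; holdout error ",
          signif(as.numeric(strat$validation), 3))

  enrich <- NULL
  if (!is.null(gene_sets)) {
    enrich <- stage("enrich",
                    spot_enrichment(spots, gene_sets,
                                    universe = names(model$gene_bmu)))
    message("[enrich] ", length(gene_sets), " gene sets x ",
            nrow(spots), " spots")
  }

  phen_overview <- NULL
  if (!is.null(phen)) {
    phen_overview <- stage("phenotype", phenotype_overview(model, phen))
    message("[phenotype] ", nrow(phen_overview), " correlation maps")
  }

  summary <- list(
    preprocess = list(n_genes = nrow(x), n_samples = ncol(x)),
    train = list(grid_rows = config$grid_rows, grid_cols = config$grid_cols,
                 epochs = config$epochs,
                 quantization_error =
                   utils::tail(model$meta$qe_history, 1)),
    spots = list(n_spots = nrow(spots), n_spot_genes = sum(spots$n_genes)),
    stratify = list(k = strat$k,
                    n_subtypes = length(unique(strat$assignment$subtype)),
                    n_cpats = length(unique(strat$cpats$cpat)),
                    misclassification = as.numeric(strat$validation)),
    enrich = list(n_sets = length(gene_sets),
                  n_tests = if (is.null(enrich)) 0L else nrow(enrich)),
    phenotype = list(n_maps = if (is.null(phen_overview)) 0L
                     else nrow(phen_overview)),
    parameters = config[setdiff(names(config),
                                c("expression", "phenotypes", "gene_sets",
                                  "out_dir"))]
  )

  out <- structure(list(model = model, spots = spots, cpats = strat$cpats,
                        assignment = strat$assignment, enrichment = enrich,
                        phenotype_overview = phen_overview,
                        validation = strat$validation, summary = summary),
                   class = "som_pipeline")
  if (!is.null(config$out_dir)) write_pipeline(out, config$out_dir)
  out
}

write_pipeline <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(tidy(res$spots), file.path(dir, "spot_genes.tsv"),
                   progress = FALSE)
  prof <- attr(res$spots, "profiles")
  if (nrow(prof)) {
    readr::write_tsv(tibble::as_tibble(prof, rownames = "spot_id"),
                     file.path(dir, "spot_profiles.tsv"), progress = FALSE)
  }
  readr::write_csv(dplyr::left_join(res$assignment, res$cpats,
                                    by = "sample_id"),
                   file.path(dir, "type_assignment.csv"), progress = FALSE)
  if (!is.null(res$enrichment)) {
    readr::write_tsv(res$enrichment, file.path(dir, "enrichment.tsv"),
                     progress = FALSE)
  }
  if (!is.null(res$phenotype_overview)) {
    readr::write_csv(res$phenotype_overview,
                     file.path(dir, "phenotype_overview.csv"),
                     progress = FALSE)
  }
  jsonlite::write_json(res$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @export
print.som_pipeline <- function(x, ...) {
  s <- x$summary
  cat("SOM portrayal pipeline:\n",
      " ", s$preprocess$n_genes, "genes x", s$preprocess$n_samples,
      "samples on a", s$train$grid_rows, "x", s$train$grid_cols, "grid\n",
      " ", s$spots$n_spots, "spots;", s$stratify$n_cpats, "cPATs;",
      s$stratify$k, "types /", s$stratify$n_subtypes, "subtypes\n",
      "  holdout misclassification:",
      signif(s$stratify$misclassification, 3), "\n")
  invisible(x)
}

#' One-row summary of a pipeline run
#'
#' @param x A `som_pipeline`.
#' @param ... Unused.
#' @return Tibble of the run's headline counts.
#' @export
glance.som_pipeline <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    n_genes = s$preprocess$n_genes, n_samples = s$preprocess$n_samples,
    n_spots = s$spots$n_spots, n_cpats = s$stratify$n_cpats,
    n_types = s$stratify$k, n_subtypes = s$stratify$n_subtypes,
    misclassification = s$stratify$misclassification,
    quantization_error = s$train$quantization_error
  )
}
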