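#' Right-tailed Fisher overrepresentation of a gene set in a spot
#'
#' Exact hypergeometric tail: with a universe of `N` genes, `K` of which
#' belong to the gene set, drawing the `n` spot genes, the p-value is
#' `P(X >= overlap)`. Equivalent to the one-sided Fisher's exact test on
#' the 2x2 membership table.
#'
#' @param spot_genes Character vector of spot member genes.
#' @param gene_set Character vector of set genes.
#' @param universe Character vector of all genes under consideration; spot
#'   and set genes outside it are dropped.
#' @return List with `overlap` and `p.value`.
#' @export
#' @examples
#' fisher_enrichment(letters[1:10], letters[1:10], letters[1:20])
fisher_enrichment <- function(spot_genes, gene_set, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty gene universe", call. = FALSE)
  spot_genes <- intersect(unique(spot_genes), universe)
  gene_set <- intersect(unique(gene_set), universe)
  q <- length(intersect(spot_genes, gene_set))
  # P(X >= q) = upper tail including q
  p <- stats::phyper(q - 1, length(gene_set),
                     length(universe) - length(gene_set),
                     length(spot_genes), lower.tail = FALSE)
  list(overlap = q, p.value = min(1, p))
}

#' Fisher enrichment of every gene set in every spot
#'
#' @param spots A `spot_set` (or named list of gene vectors).
#' @param gene_sets Named list of gene id vectors (e.g. from [read_gmt()]).
#' @param universe Gene universe; defaults to the union of all spot genes
#'   and set genes present in the map when `spots` is a `spot_set` (then
#'   all mapped genes).
#' @return Tibble (`spot_id`, `set`, `n_spot`, `n_set`, `overlap`, `p`,
#'   `fdr`), FDR by Benjamini-Hochberg across all cells.
#' @export
spot_enrichment <- function(spots, gene_sets, universe) {
  spot_list <- if (inherits(spots, "spot_set")) {
    stats::setNames(spots$genes, spots$spot_id)
  } else {
    spots
  }
  grid <- tidyr::expand_grid(spot_id = names(spot_list),
                             set = names(gene_sets))
  res <- purrr::pmap_dfr(grid, function(spot_id, set) {
    fe <- fisher_enrichment(spot_list[[spot_id]], gene_sets[[set]], universe)
    tibble::tibble(spot_id = spot_id, set = set,
                   n_spot = length(intersect(spot_list[[spot_id]], universe)),
                   n_set = length(intersect(gene_sets[[set]], universe)),
                   overlap = fe$overlap, p = fe$p.value)
  })
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  dplyr::arrange(res, .data$p)
}

#' Sample-wise gene-set z-score (GSZ)
#'
#' Scores the activation of a gene set in one sample: the difference
#' between the set's mean expression and the universe mean, normalized by
#' a pooled variance and scaled by the square root of the set size,
#'
#' `GSZ = sqrt(n_S) * (mean_S - mean_U) / sqrt(w * var_S + (1 - w) * var_U)`
#'
#' with population (1/n) variances and pooling weight `w` (default 0.5).
#' Homogeneously activated sets (large mean shift, small internal
#' variance) score high. Returns 0 when the denominator is 0; a singleton
#' set's undefined variance term is replaced by the universe variance.
#'
#' @param sample_expression Named numeric vector: one sample's (centered)
#'   expression over the gene universe.
#' @param gene_set Character vector of set genes.
#' @param w Pooling weight on the set variance (default 0.5).
#' @return Scalar score.
#' @export
gsz <- function(sample_expression, gene_set, w = 0.5) {
  e <- sample_expression
  if (is.null(names(e))) stop("sample_expression must be named by gene id",
                              call. = FALSE)
  set_idx <- names(e) %in% gene_set
  n_s <- sum(set_idx)
  if (n_s == 0) stop("gene set does not intersect the universe", call. = FALSE)
  pop_var <- function(v) mean((v - mean(v))^2)
  m_s <- mean(e[set_idx]); m_u <- mean(e)
  v_u <- pop_var(e)
  v_s <- if (n_s >= 2) pop_var(e[set_idx]) else v_u
  denom <- sqrt(w * v_s + (1 - w) * v_u)
  if (denom == 0) return(0)
  num <- sqrt(n_s) * (m_s - m_u)
  if (num == 0) return(0)
  num / denom
}

#' GSZ scores for several gene sets across all samples
#'
#' @param x Centered genes x samples expression matrix.
#' @param gene_sets Named list of gene id vectors.
#' @param w Pooling weight, see [gsz()].
#' @return Tibble (`sample_id`, `set`, `gsz`).
#' @export
gsz_scores <- function(x, gene_sets, w = 0.5) {
  x <- as.matrix(x)
  purrr::map_dfr(names(gene_sets), function(nm) {
    tibble::tibble(
      sample_id = colnames(x),
      set = nm,
      gsz = vapply(seq_len(ncol(x)), function(j) {
        gsz(stats::setNames(x[, j], rownames(x)), gene_sets[[nm]], w = w)
      }, 1)
    )
  })
}

#' Gene-set map: where a set's genes sit on the grid
#'
#' Counts, for every map unit, the set genes whose best-matching unit it
#' is; accumulation in or near spots indicates the set's functional
#' context.
#'
#' @param model A `som_model`.
#' @param gene_set Character vector of gene ids.
#' @return `grid_rows x grid_cols` integer matrix; counts sum to the
#'   number of set genes present in the model. Warns when none map.
#' @export
gene_set_map <- function(model, gene_set) {
  stopifnot(inherits(model, "som_model"))
  bmu <- model$gene_bmu[names(model$gene_bmu) %in% gene_set]
  if (length(bmu) == 0) {
    warning("no gene of the set is present in the model", call. = FALSE)
  }
  counts <- tabulate(bmu, nbins = model$grid_rows * model$grid_cols)
  matrix(counts, model$grid_rows, model$grid_cols, byrow = TRUE)
}
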