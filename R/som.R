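#' Train a self-organizing map of gene expression profiles
#'
#' Batch-trains a planar (non-toroidal) SOM whose data points are gene rows
#' of a centered genes x samples matrix. Each of the `grid_rows *
#' grid_cols` units carries a codebook vector over samples (a "metagene", a
#' micro-cluster profile of co-expressed genes). Per epoch every gene is
#' assigned to its nearest codebook vector (Euclidean; ties broken toward
#' the lowest unit index), then each unit is replaced by the Gaussian
#' neighborhood-weighted mean of assigned genes. The neighborhood radius
#' decays linearly from `radius_start` (default `max(grid_rows,
#' grid_cols) / 2`) to `radius_end` over the epochs. Units whose
#' neighborhood weight mass is zero keep their previous vector.
#'
#' Initialization spans the plane of the first two principal components of
#' the gene profiles (eigenvectors of the sample-space cross-product, with
#' a deterministic sign convention), falling back to a seeded random sample
#' of gene rows when the covariance is degenerate. Batch updates make the
#' result order-independent and deterministic given the seed.
#'
#' @param x Centered numeric matrix, genes x samples, with dimnames.
#' @param grid_rows,grid_cols Grid dimensions (default 16 x 16; population
#'   scale typically uses 100 x 100).
#' @param epochs Number of batch epochs (default 20).
#' @param radius_start,radius_end Neighborhood radius schedule.
#' @param seed Integer seed (used by the random fallback initialization).
#' @return An object of class `som_model`: list with `codebook` (K x
#'   n_samples), `grid_rows`, `grid_cols`, `gene_bmu` (named integer vector
#'   of best-matching units), `sample_ids`, `meta` (epochs, radii, seed,
#'   per-epoch quantization error).
#' @export
train_som <- function(x, grid_rows = 16, grid_cols = 16, epochs = 20,
                      radius_start = NULL, radius_end = 0.5, seed = 1L) {
  x <- as.matrix(x)
  K <- as.integer(grid_rows) * as.integer(grid_cols)
  if (K < 1L || nrow(x) < 1L || ncol(x) < 1L) {
    stop("need a non-empty expression matrix and at least one grid unit",
         call. = FALSE)
  }
  if (nrow(x) < K) {
    warning("fewer genes (", nrow(x), ") than map units (", K,
            "); consider a smaller grid", call. = FALSE)
  }
  if (is.null(rownames(x))) rownames(x) <- sprintf("g%d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("S%d", seq_len(ncol(x)))
  if (is.null(radius_start)) radius_start <- max(grid_rows, grid_cols) / 2

  coords <- grid_coordinates(grid_rows, grid_cols)
  d2grid <- as.matrix(stats::dist(coords[, c("row", "col")]))^2

  C <- som_init(x, coords, seed)
  radii <- if (epochs > 1) {
    seq(radius_start, radius_end, length.out = epochs)
  } else {
    radius_end
  }
  xsq <- rowSums(x^2)
  qe_history <- numeric(epochs)
  bmu <- rep(1L, nrow(x))
  for (e in seq_len(epochs)) {
    D2 <- bmu_distances(x, C, xsq)
    bmu <- max.col(-D2, ties.method = "first")
    sigma <- radii[e]
    H <- exp(-d2grid / (2 * sigma^2))
    counts <- tabulate(bmu, nbins = K)
    sums <- matrix(0, K, ncol(x))
    rs <- rowsum(x, group = bmu, reorder = TRUE)
    sums[as.integer(rownames(rs)), ] <- rs
    den <- as.vector(H %*% counts)
    num <- H %*% sums
    upd <- den > 0
    C[upd, ] <- num[upd, , drop = FALSE] / den[upd]
    D2 <- bmu_distances(x, C, xsq)
    bmu <- max.col(-D2, ties.method = "first")
    qe_history[e] <- mean(sqrt(pmax(D2[cbind(seq_len(nrow(x)), bmu)], 0)))
  }
  colnames(C) <- colnames(x)
  names(bmu) <- rownames(x)
  structure(list(
    codebook = C,
    grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
    gene_bmu = bmu,
    sample_ids = colnames(x),
    meta = list(epochs = epochs, radius_start = radius_start,
                radius_end = radius_end, seed = as.integer(seed),
                qe_history = qe_history)
  ), class = "som_model")
}

# Row-major unit layout: unit k sits at row (k-1) %/% cols + 1,
# col (k-1) %% cols + 1.
grid_coordinates <- function(grid_rows, grid_cols) {
  k <- seq_len(grid_rows * grid_cols)
  tibble::tibble(unit = k,
                 row = (k - 1L) %/% grid_cols + 1L,
                 col = (k - 1L) %% grid_cols + 1L)
}

som_init <- function(x, coords, seed) {
  K <- nrow(coords)
  n_s <- ncol(x)
  mu <- colMeans(x)
  ok <- FALSE
  if (n_s >= 2 && nrow(x) >= 2) {
    cp <- crossprod(sweep(x, 2, mu))
    eg <- eigen(cp, symmetric = TRUE)
    if (eg$values[2] > 1e-12 * max(eg$values[1], 1)) {
      # deterministic sign: largest-magnitude loading positive
      v1 <- eg$vectors[, 1]; v2 <- eg$vectors[, 2]
      if (v1[which.max(abs(v1))] < 0) v1 <- -v1
      if (v2[which.max(abs(v2))] < 0) v2 <- -v2
      s1 <- sqrt(eg$values[1] / max(nrow(x) - 1, 1))
      s2 <- sqrt(eg$values[2] / max(nrow(x) - 1, 1))
      g1 <- scale_to_unit(coords$col)
      g2 <- scale_to_unit(coords$row)
      C <- outer(rep(1, K), mu) + 2 * s1 * outer(g1, v1) +
        2 * s2 * outer(g2, v2)
      ok <- TRUE
    }
  }
  if (!ok) {
    set.seed(seed)
    idx <- sample.int(nrow(x), K, replace = nrow(x) < K)
    C <- x[idx, , drop = FALSE] +
      matrix(stats::rnorm(K * n_s, sd = 1e-6), K, n_s)
  }
  unname(as.matrix(C))
}

scale_to_unit <- function(v) {
  r <- range(v)
  if (diff(r) == 0) return(rep(0, length(v)))
  2 * (v - r[1]) / diff(r) - 1
}

bmu_distances <- function(x, C, xsq = rowSums(x^2)) {
  # squared Euclidean distances genes x units
  sweep(-2 * tcrossprod(x, C), 1, -xsq) + rep(rowSums(C^2), each = nrow(x))
}

#' Render a sample's expression portrait
#'
#' Reshapes one sample's codebook column onto the map grid (row-major),
#' giving the "personalized image" of that sample's transcriptome.
#'
#' @param model A [train_som()] model.
#' @param sample Sample id (or column index).
#' @return Object of class `som_portrait`: list with `sample_id` and `grid`
#'   (grid_rows x grid_cols matrix).
#' @export
portrait <- function(model, sample) {
  stopifnot(inherits(model, "som_model"))
  if (is.character(sample)) {
    j <- match(sample, model$sample_ids)
    if (is.na(j)) stop("unknown sample id: ", sample, call. = FALSE)
  } else {
    j <- as.integer(sample)
    if (j < 1 || j > length(model$sample_ids)) {
      stop("sample index out of range", call. = FALSE)
    }
  }
  g <- matrix(model$codebook[, j], nrow = model$grid_rows,
              ncol = model$grid_cols, byrow = TRUE)
  structure(list(sample_id = model$sample_ids[j], grid = g),
            class = "som_portrait")
}

#' Flatten a portrait back to its codebook column
#'
#' Inverse of [portrait()]: returns the unit-ordered vector.
#' @param p A `som_portrait`.
#' @return Numeric vector of length K.
#' @export
flatten_portrait <- function(p) {
  as.vector(t(p$grid))
}

#' Mean portrait of a sample group
#'
#' Element-wise mean of the member portraits, the group-level summary image
#' used for transcriptome types and subtypes.
#'
#' @param model A `som_model`.
#' @param samples Non-empty vector of sample ids (or indices).
#' @return A `som_portrait` whose `sample_id` names the group.
#' @export
mean_portrait <- function(model, samples) {
  stopifnot(inherits(model, "som_model"))
  if (length(samples) == 0) stop("empty sample subset", call. = FALSE)
  grids <- lapply(samples, function(s) portrait(model, s)$grid)
  g <- Reduce(`+`, grids) / length(grids)
  structure(list(sample_id = sprintf("mean(n=%d)", length(grids)), grid = g),
            class = "som_portrait")
}

#' Mean quantization error of a trained map
#'
#' Mean Euclidean distance from each gene profile to its best-matching
#' unit's codebook vector; the standard SOM fit diagnostic.
#'
#' @param model A `som_model`.
#' @param x The (centered) expression matrix the model was trained on.
#' @return Non-negative scalar.
#' @export
quantization_error <- function(model, x) {
  stopifnot(inherits(model, "som_model"))
  x <- as.matrix(x)
  if (ncol(x) != ncol(model$codebook)) {
    stop("sample dimension mismatch between matrix and model", call. = FALSE)
  }
  D2 <- bmu_distances(x, model$codebook)
  bmu <- max.col(-D2, ties.method = "first")
  mean(sqrt(pmax(D2[cbind(seq_len(nrow(x)), bmu)], 0)))
}

#' @export
print.som_model <- function(x, ...) {
  cat("SOM model:", x$grid_rows, "x", x$grid_cols, "grid (",
      x$grid_rows * x$grid_cols, "metagenes ),",
      length(x$gene_bmu), "genes,", length(x$sample_ids), "samples\n")
  cat("  epochs:", x$meta$epochs, " final quantization error:",
      signif(utils::tail(x$meta$qe_history, 1), 4), "\n")
  invisible(x)
}

#' @export
print.som_portrait <- function(x, ...) {
  cat("Portrait of", x$sample_id, "(", nrow(x$grid), "x", ncol(x$grid),
      "); range", signif(min(x$grid), 3), "..", signif(max(x$grid), 3), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-unit summary of a SOM model
#'
#' @param x A `som_model`.
#' @param ... Unused.
#' @return Tibble with one row per grid unit: `unit`, `row`, `col`,
#'   `n_genes` assigned.
#' @export
tidy.som_model <- function(x, ...) {
  co <- grid_coordinates(x$grid_rows, x$grid_cols)
  co$n_genes <- tabulate(x$gene_bmu, nbins = nrow(co))
  co
}

#' One-row summary of a SOM model
#'
#' @param x A `som_model`.
#' @param ... Unused.
#' @return Tibble with grid size, gene/sample counts, epochs, final
#'   quantization error and the fraction of occupied units.
#' @export
glance.som_model <- function(x, ...) {
  K <- x$grid_rows * x$grid_cols
  tibble::tibble(
    grid_rows = x$grid_rows, grid_cols = x$grid_cols, k = K,
    n_genes = length(x$gene_bmu), n_samples = length(x$sample_ids),
    epochs = x$meta$epochs,
    quantization_error = utils::tail(x$meta$qe_history, 1),
    frac_units_occupied = mean(tabulate(x$gene_bmu, nbins = K) > 0)
  )
}
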