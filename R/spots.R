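#' Overexpression summary map
#'
#' Per-unit summary of how strongly each metagene is ever overexpressed:
#' the `prob` quantile (default the 98th percentile) of the unit's codebook
#' values across samples, arranged on the grid. High-summary areas are the
#' red "spot" regions of the portraits.
#'
#' @param model A [train_som()] model.
#' @param prob Quantile across samples (default 0.98).
#' @return `grid_rows x grid_cols` matrix (row-major unit layout).
#' @export
overexpression_summary <- function(model, prob = 0.98) {
  stopifnot(inherits(model, "som_model"))
  s <- apply(model$codebook, 1, stats::quantile, probs = prob, names = FALSE)
  matrix(s, model$grid_rows, model$grid_cols, byrow = TRUE)
}

#' U-matrix of a trained map
#'
#' For every unit, the mean Euclidean distance between its codebook vector
#' and those of its 8-connected grid neighbors (fewer at borders). Ridges
#' of large distance form the closed halo-like lines that separate
#' co-expression domains.
#'
#' @param model A `som_model`.
#' @return `grid_rows x grid_cols` non-negative matrix.
#' @export
compute_umatrix <- function(model) {
  stopifnot(inherits(model, "som_model"))
  R <- model$grid_rows; Cn <- model$grid_cols
  C <- model$codebook
  U <- matrix(0, R, Cn)
  for (r in seq_len(R)) {
    for (cc in seq_len(Cn)) {
      k <- (r - 1L) * Cn + cc
      nb <- neighbor_units(r, cc, R, Cn)
      d <- sqrt(rowSums((C[nb, , drop = FALSE] -
                           rep(C[k, ], each = length(nb)))^2))
      U[r, cc] <- mean(d)
    }
  }
  U
}

neighbor_units <- function(r, cc, R, Cn) {
  rr <- pmax(1L, r - 1L):pmin(R, r + 1L)
  ccc <- pmax(1L, cc - 1L):pmin(Cn, cc + 1L)
  g <- expand.grid(row = rr, col = ccc)
  g <- g[!(g$row == r & g$col == cc), , drop = FALSE]
  (g$row - 1L) * Cn + g$col
}

#' Segment overexpression spot modules from the metagene map
#'
#' Operationalizes the distance-metrics spot criterion: (i) select
#' candidate units from the overexpression summary map; (ii) build the
#' 8-neighbor adjacency over candidates, cutting every edge whose
#' codebook distance exceeds the `ridge_quantile` of all neighbor-pair
#' distances in the map — the halo-like barrier lines of large
#' metagene-to-metagene distance that close around spots; (iii) label the
#' resulting connected components; (iv) drop components smaller than
#' `min_units` or without member genes; (v) keep the `max_spots` largest
#' and letter them `A`, `B`, ... in decreasing gene count. Member genes
#' are the genes whose best-matching unit lies in the spot; the spot
#' profile is the mean codebook value over its units, one value per
#' sample.
#'
#' Candidate selection: with the default `top_quantile = NULL`, the summary
#' values are split into a low and a high regime by two-class 1-D k-means
#' and the high class is kept — a scale-free criterion that works across
#' grid sizes. A numeric `top_quantile` instead keeps units whose summary
#' exceeds that quantile of the summary map (the fixed-rank rule suited to
#' large population-scale grids, e.g. 0.98 on a 100 x 100 map).
#'
#' @param model A `som_model`.
#' @param top_quantile `NULL` (two-regime split, default) or a quantile in
#'   (0, 1) applied to the summary map.
#' @param ridge_quantile Quantile of the neighbor-pair codebook distances
#'   above which an adjacency is treated as a barrier ridge (default
#'   0.85).
#' @param min_units Minimum units per spot; the default `NULL` scales the
#'   spot core with map area, `max(1, K / 200)` for `K` units (1 on a
#'   16 x 16 map, 50 at population scale 100 x 100).
#' @param min_genes Minimum member genes per reported spot (default 5): a
#'   handful of stray genes is not a co-expression module.
#' @param max_spots Maximum number of spots reported (default 25).
#' @param summary,umatrix Optional precomputed maps (else computed here).
#' @return A `spot_set`: tibble with one row per spot (`spot_id`,
#'   `n_units`, `n_genes`, list-columns `units` and `genes`) carrying the
#'   spot-by-sample profile matrix in `attr(, "profiles")` plus the summary
#'   and U-matrix used.
#' @export
detect_spots <- function(model, top_quantile = NULL, ridge_quantile = 0.85,
                         min_units = NULL, min_genes = 5, max_spots = 25,
                         summary = NULL, umatrix = NULL) {
  stopifnot(inherits(model, "som_model"))
  if (is.null(summary)) summary <- overexpression_summary(model)
  if (is.null(umatrix)) umatrix <- compute_umatrix(model)
  stopifnot(all(dim(summary) == c(model$grid_rows, model$grid_cols)),
            all(dim(umatrix) == dim(summary)))
  if (is.null(min_units)) {
    min_units <- max(1L, (model$grid_rows * model$grid_cols) %/% 200L)
  }

  cand <- candidate_mask(summary, top_quantile)
  # spots are gene micro-clusters: units with no assigned gene are smooth
  # interpolation between domains, not spot material
  occupied <- tabulate(model$gene_bmu,
                       nbins = model$grid_rows * model$grid_cols) > 0
  cand <- cand & matrix(occupied, model$grid_rows, model$grid_cols,
                        byrow = TRUE)
  labels <- label_components(cand, codebook = model$codebook,
                             ridge_quantile = ridge_quantile)
  comp_ids <- setdiff(unique(as.vector(labels)), 0L)

  spots <- list()
  for (id in comp_ids) {
    idx <- which(t(labels) == id)  # unit indices, row-major
    if (length(idx) < min_units) next
    genes <- names(model$gene_bmu)[model$gene_bmu %in% idx]
    if (length(genes) < max(1, min_genes)) next
    spots[[length(spots) + 1L]] <- list(units = sort(idx), genes = genes)
  }
  if (length(spots) > max_spots) {
    keep <- order(vapply(spots, function(s) length(s$units), 1L),
                  decreasing = TRUE)[seq_len(max_spots)]
    spots <- spots[sort(keep)]
  }
  ord <- order(vapply(spots, function(s) length(s$genes), 1L),
               decreasing = TRUE)
  spots <- spots[ord]
  ids <- spot_letters(length(spots))

  profiles <- matrix(numeric(0), 0, length(model$sample_ids),
                     dimnames = list(NULL, model$sample_ids))
  if (length(spots)) {
    profiles <- t(vapply(spots, function(s) {
      colMeans(model$codebook[s$units, , drop = FALSE])
    }, numeric(length(model$sample_ids))))
    dimnames(profiles) <- list(ids, model$sample_ids)
  }
  out <- tibble::tibble(
    spot_id = ids,
    n_units = vapply(spots, function(s) length(s$units), 1L),
    n_genes = vapply(spots, function(s) length(s$genes), 1L),
    units = lapply(spots, `[[`, "units"),
    genes = lapply(spots, `[[`, "genes")
  )
  attr(out, "profiles") <- profiles
  attr(out, "grid_rows") <- model$grid_rows
  attr(out, "grid_cols") <- model$grid_cols
  attr(out, "summary") <- summary
  attr(out, "umatrix") <- umatrix
  attr(out, "params") <- list(top_quantile = top_quantile,
                              ridge_quantile = ridge_quantile,
                              min_units = min_units, min_genes = min_genes,
                              max_spots = max_spots)
  class(out) <- c("spot_set", class(out))
  out
}

candidate_mask <- function(summary, top_quantile) {
  if (!is.null(top_quantile)) {
    stopifnot(top_quantile > 0, top_quantile < 1)
    return(summary > stats::quantile(summary, top_quantile, names = FALSE))
  }
  v <- as.vector(summary)
  if (diff(range(v)) == 0) return(summary > Inf)
  km <- stats::kmeans(v, centers = matrix(range(v), ncol = 1))
  hi <- which.max(km$centers)
  matrix(km$cluster == hi, nrow(summary), ncol(summary))
}

# 8-connected component labeling of a logical grid mask (flood fill).
# With a codebook, adjacency is additionally gated by the halo criterion:
# two neighboring units connect only when their codebook distance is at or
# below the ridge_quantile of all neighbor-pair distances in the map.
label_components <- function(mask, codebook = NULL, ridge_quantile = NULL) {
  R <- nrow(mask); Cn <- ncol(mask)
  thr <- Inf
  if (!is.null(codebook) && !is.null(ridge_quantile)) {
    thr <- stats::quantile(neighbor_distances(codebook, R, Cn),
                           ridge_quantile, names = FALSE)
  }
  edge_ok <- function(k1, k2) {
    if (!is.finite(thr)) return(TRUE)
    sqrt(sum((codebook[k1, ] - codebook[k2, ])^2)) <= thr
  }
  labels <- matrix(0L, R, Cn)
  current <- 0L
  for (r0 in seq_len(R)) {
    for (c0 in seq_len(Cn)) {
      if (!mask[r0, c0] || labels[r0, c0] != 0L) next
      current <- current + 1L
      queue <- matrix(c(r0, c0), ncol = 2)
      labels[r0, c0] <- current
      while (nrow(queue)) {
        r <- queue[1, 1]; cc <- queue[1, 2]
        queue <- queue[-1, , drop = FALSE]
        for (dr in -1:1) for (dc in -1:1) {
          if (dr == 0 && dc == 0) next
          nr <- r + dr; nc <- cc + dc
          if (nr < 1 || nr > R || nc < 1 || nc > Cn) next
          if (mask[nr, nc] && labels[nr, nc] == 0L &&
              edge_ok((r - 1L) * Cn + cc, (nr - 1L) * Cn + nc)) {
            labels[nr, nc] <- current
            queue <- rbind(queue, c(nr, nc))
          }
        }
      }
    }
  }
  labels
}

# Euclidean codebook distances of every 8-neighbor unit pair (each pair
# once), the distance distribution underlying the halo/ridge criterion.
neighbor_distances <- function(codebook, R, Cn) {
  d <- numeric(0)
  for (r in seq_len(R)) {
    for (cc in seq_len(Cn)) {
      k <- (r - 1L) * Cn + cc
      # right, down-left, down, down-right cover each pair exactly once
      nbs <- list(c(r, cc + 1L), c(r + 1L, cc - 1L), c(r + 1L, cc),
                  c(r + 1L, cc + 1L))
      for (nb in nbs) {
        if (nb[1] < 1 || nb[1] > R || nb[2] < 1 || nb[2] > Cn) next
        k2 <- (nb[1] - 1L) * Cn + nb[2]
        d <- c(d, sqrt(sum((codebook[k, ] - codebook[k2, ])^2)))
      }
    }
  }
  d
}

spot_letters <- function(n) {
  if (n == 0) return(character(0))
  if (n <= 26) return(LETTERS[seq_len(n)])
  extra <- as.vector(outer(LETTERS, LETTERS, function(a, b) paste0(a, b)))
  c(LETTERS, extra)[seq_len(n)]
}

#' Spot-by-sample expression profiles
#'
#' @param spots A `spot_set`.
#' @param spot_id Optional single spot id; default all.
#' @return Matrix spots x samples (or a named vector for one spot).
#' @export
spot_profiles <- function(spots, spot_id = NULL) {
  stopifnot(inherits(spots, "spot_set"))
  p <- attr(spots, "profiles")
  if (is.null(spot_id)) return(p)
  if (!spot_id %in% rownames(p)) stop("unknown spot id: ", spot_id, call. = FALSE)
  p[spot_id, ]
}

#' Mean codebook expression of a unit set, per sample
#'
#' @param model A `som_model`.
#' @param units Non-empty vector of unit indices (row-major).
#' @return Named numeric vector over samples.
#' @export
spot_expression <- function(model, units) {
  stopifnot(inherits(model, "som_model"))
  if (length(units) == 0) stop("empty unit set", call. = FALSE)
  if (any(units < 1 | units > nrow(model$codebook))) {
    stop("unit indices outside the grid", call. = FALSE)
  }
  colMeans(model$codebook[units, , drop = FALSE])
}

#' Spot-to-spot correlation network
#'
#' Pearson correlations between spot expression profiles; edges where
#' `|r| >= r_threshold`, signed by the correlation sign. Zero-variance
#' profiles correlate 0 (no edge).
#'
#' @param spots A `spot_set` with at least two spots.
#' @param r_threshold Absolute correlation threshold (default 0.5).
#' @return Tibble edge list: `spot_a`, `spot_b`, `r`, `sign`.
#' @export
spot_correlation_network <- function(spots, r_threshold = 0.5) {
  stopifnot(inherits(spots, "spot_set"))
  p <- attr(spots, "profiles")
  if (nrow(p) < 2) stop("need at least two spots", call. = FALSE)
  sds <- apply(p, 1, stats::sd)
  R <- matrix(0, nrow(p), nrow(p), dimnames = list(rownames(p), rownames(p)))
  ok <- sds > 0
  if (sum(ok) >= 2) R[ok, ok] <- stats::cor(t(p[ok, , drop = FALSE]))
  pairs <- which(upper.tri(R), arr.ind = TRUE)
  r_all <- R[pairs]
  keep <- abs(r_all) >= r_threshold
  r_kept <- r_all[keep]
  tibble::tibble(
    spot_a = rownames(R)[pairs[keep, 1]],
    spot_b = rownames(R)[pairs[keep, 2]],
    r = r_kept,
    sign = ifelse(r_kept >= 0, "positive", "negative")
  )
}

#' Long per-gene view of a spot set
#'
#' @param x A `spot_set`.
#' @param ... Unused.
#' @return Tibble (`spot_id`, `gene_id`), mirroring the supplementary
#'   spot gene lists of portrayal studies.
#' @export
tidy.spot_set <- function(x, ...) {
  tibble::tibble(
    spot_id = rep(x$spot_id, lengths(x$genes)),
    gene_id = unlist(x$genes, use.names = FALSE)
  )
}

#' @export
print.spot_set <- function(x, ...) {
  cat("Spot set:", nrow(x), "spots;",
      sum(x$n_genes), "member genes on a",
      attr(x, "grid_rows"), "x", attr(x, "grid_cols"), "grid\n")
  NextMethod()
}
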