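#' Assign combinatorial pattern types (cPATs)
#'
#' A sample's cPAT is the set of spots over-expressed in it: spot `s` is in
#' the set iff the sample's spot expression, z-scored across samples within
#' the spot, exceeds `z_threshold`. Zero-variance spot profiles are never
#' over-expressed. The cPAT is encoded as the sorted spot ids joined with
#' `"+"` (empty pattern = `""`).
#'
#' @param spots A `spot_set` from [detect_spots()].
#' @param z_threshold Over-expression criterion on the spot z-score
#'   (default 1.0).
#' @return Tibble (`sample_id`, `cpat`).
#' @export
assign_cpats <- function(spots, z_threshold = 1.0) {
  stopifnot(inherits(spots, "spot_set"))
  p <- attr(spots, "profiles")
  if (nrow(p) == 0) {
    return(tibble::tibble(sample_id = colnames(p), cpat = character(0)))
  }
  sds <- apply(p, 1, stats::sd)
  z <- (p - rowMeans(p)) / ifelse(sds > 0, sds, Inf)
  over <- z > z_threshold
  cpat <- apply(over, 2, function(v) paste(rownames(p)[v], collapse = "+"))
  tibble::tibble(sample_id = colnames(p), cpat = unname(cpat))
}

#' Count cPATs and flag the frequent ones
#'
#' @param cpats Tibble from [assign_cpats()].
#' @param min_count Patterns observed at least this often are flagged
#'   `major` (default 5).
#' @return Tibble (`cpat`, `n`, `major`), sorted by decreasing count.
#' @export
enumerate_cpats <- function(cpats, min_count = 5) {
  cpats |>
    dplyr::count(.data$cpat, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$cpat) |>
    dplyr::mutate(major = .data$n >= min_count)
}

#' Estimate the tentative number of transcriptome types
#'
#' Computes the centroid portrait (mean metagene vector) of every major
#' cPAT, clusters the centroids by average-linkage hierarchical clustering
#' on Euclidean distance, and cuts the tree at the largest merge-height
#' gap; the number of clusters there, bounded to `[2, n_major]`, is the
#' tentative type count fed to the K-means stratification.
#'
#' @param model A `som_model`.
#' @param cpats Tibble from [assign_cpats()].
#' @param min_count Passed to [enumerate_cpats()].
#' @return Integer `k`, with the centroid `hclust` tree in
#'   `attr(, "tree")` and the pattern table in `attr(, "cpat_table")`.
#' @export
estimate_type_count <- function(model, cpats, min_count = 5) {
  stopifnot(inherits(model, "som_model"))
  tab <- enumerate_cpats(cpats, min_count)
  major <- tab$cpat[tab$major]
  if (length(major) == 0) {
    stop("no major cPAT at min_count = ", min_count, call. = FALSE)
  }
  if (length(major) == 1) {
    warning("single major cPAT; k = 1", call. = FALSE)
    k <- 1L
    attr(k, "cpat_table") <- tab
    return(k)
  }
  cent <- vapply(major, function(cp) {
    ids <- cpats$sample_id[cpats$cpat == cp]
    rowMeans(model$codebook[, ids, drop = FALSE])
  }, numeric(nrow(model$codebook)))
  tree <- stats::hclust(stats::dist(t(cent)), method = "average")
  h <- tree$height
  if (length(h) == 1 || diff(range(h)) == 0) {
    warning("degenerate centroid tree; k forced to 2", call. = FALSE)
    k <- 2L
  } else {
    gaps <- diff(c(0, h))
    # merge heights ascend; cutting below the largest gap leaves
    # n_major - (index of that merge) + 1 clusters
    k <- length(major) - which.max(gaps[-1]) + 0L
    k <- max(2L, min(k, length(major)))
  }
  attr(k, "tree") <- tree
  attr(k, "cpat_table") <- tab
  k
}

#' Stratify samples into transcriptome types and subtypes
#'
#' K-means (k-means++-style seeding via multiple restarts, seeded,
#' `nstart = 25`) on the samples' full metagene vectors yields `k` types;
#' a second K-means within each type yields `n_subtypes` subtypes
#' (labelled `"<type>.<j>"`). Labels are deterministically re-ordered:
#' types are ranked by their centroids' mean expression of the reference
#' spot (the largest spot by default), the lowest-expression type becoming
#' `"1"`; when `k = 3` the type whose centroid correlates least in
#' absolute mean with the two extremes is named `"M"`. Subtypes within a
#' type are ordered by size.
#'
#' @param model A `som_model`.
#' @param k Number of types.
#' @param n_subtypes Subtypes per type (default 3; `1` disables).
#' @param spots Optional `spot_set` providing the reference spot for the
#'   relabeling rule; without it the first principal-component score is
#'   used.
#' @param reference_spot Spot id used to anchor type ordering (default the
#'   largest spot).
#' @param seed Integer seed for the K-means restarts.
#' @return A `type_assignment` tibble (`sample_id`, `type`, `subtype`).
#' @export
cluster_types <- function(model, k, n_subtypes = 3, spots = NULL,
                          reference_spot = NULL, seed = 1L) {
  stopifnot(inherits(model, "som_model"), k >= 1)
  X <- t(model$codebook)  # samples x metagenes
  if (k > nrow(X)) stop("k exceeds the number of samples", call. = FALSE)
  set.seed(seed)
  km <- stats::kmeans(X, centers = k, nstart = 25, iter.max = 100)

  ## anchor score per cluster: mean expression of the reference spot
  anchor <- if (!is.null(spots) && nrow(spots) > 0) {
    if (is.null(reference_spot)) reference_spot <- spots$spot_id[1]
    units <- spots$units[[match(reference_spot, spots$spot_id)]]
    as.vector(rowMeans(km$centers[, units, drop = FALSE]))
  } else {
    pc1 <- stats::prcomp(X, center = TRUE, rank. = 1)$x[, 1]
    tapply(pc1, km$cluster, mean)[as.character(seq_len(k))]
  }

  labels <- rank_type_labels(km$centers, anchor)
  type <- labels[km$cluster]

  subtype <- type
  if (n_subtypes > 1) {
    for (t in unique(type)) {
      idx <- which(type == t)
      ns <- min(n_subtypes, length(idx))
      if (ns < 2) {
        subtype[idx] <- paste0(t, ".1")
        next
      }
      set.seed(seed + 1L)
      km2 <- stats::kmeans(X[idx, , drop = FALSE], centers = ns,
                           nstart = 25, iter.max = 100)
      sizes <- order(tabulate(km2$cluster, ns), decreasing = TRUE)
      relab <- integer(ns); relab[sizes] <- seq_len(ns)
      subtype[idx] <- paste0(t, ".", relab[km2$cluster])
    }
  }
  structure(
    tibble::tibble(sample_id = model$sample_ids, type = type,
                   subtype = subtype),
    class = c("type_assignment", class(tibble::tibble())),
    k = k, n_subtypes = n_subtypes
  )
}

# Deterministic type naming: order clusters by anchor score; the lowest is
# "1", the highest is "2" (for k >= 2); with k = 3 the remaining cluster is
# "M" when its centroid is the correlation-intermediate one, otherwise
# intermediate clusters are numbered onward.
rank_type_labels <- function(centers, anchor) {
  k <- nrow(centers)
  ord <- order(anchor)
  labels <- character(k)
  if (k == 1) {
    labels[ord] <- "1"
  } else if (k == 2) {
    labels[ord] <- c("1", "2")
  } else if (k == 3) {
    # extremes = the most anti-correlated centroid pair; the remaining
    # (correlation-intermediate) cluster is "M"; "1" is the extreme with
    # the lower anchor score
    r <- suppressWarnings(stats::cor(t(centers)))
    r[!is.finite(r)] <- 0
    pair <- which(r == min(r[upper.tri(r)]), arr.ind = TRUE)[1, ]
    extremes <- sort(as.integer(pair))
    mid <- setdiff(seq_len(3), extremes)
    extremes <- extremes[order(anchor[extremes])]
    labels[extremes] <- c("1", "2")
    labels[mid] <- "M"
  } else {
    labels[ord] <- c("1", paste0("M", seq_len(k - 2)), "2")
  }
  labels
}

#' Pairwise Pearson correlation between sample portraits
#'
#' @param model A `som_model` (needs >= 2 samples).
#' @return Symmetric samples x samples matrix with unit diagonal;
#'   zero-variance portraits get 0 off-diagonal.
#' @export
pairwise_correlation <- function(model) {
  stopifnot(inherits(model, "som_model"))
  C <- model$codebook
  if (ncol(C) < 2) stop("need at least two samples", call. = FALSE)
  sds <- apply(C, 2, stats::sd)
  R <- matrix(0, ncol(C), ncol(C),
              dimnames = list(colnames(C), colnames(C)))
  ok <- sds > 0
  if (sum(ok) >= 2) R[ok, ok] <- stats::cor(C[, ok, drop = FALSE])
  diag(R) <- 1
  R
}

#' Similarity-network edge list of samples
#'
#' Edges between samples whose portrait correlation exceeds a threshold;
#' feed to igraph for the correlation-network view of cohort diversity.
#'
#' @param model A `som_model`.
#' @param r_threshold Correlation threshold (default 0.5).
#' @return Tibble (`sample_a`, `sample_b`, `r`).
#' @export
similarity_network <- function(model, r_threshold = 0.5) {
  R <- pairwise_correlation(model)
  pairs <- which(upper.tri(R), arr.ind = TRUE)
  r_all <- R[pairs]
  keep <- r_all >= r_threshold
  tibble::tibble(sample_a = rownames(R)[pairs[keep, 1]],
                 sample_b = rownames(R)[pairs[keep, 2]],
                 r = r_all[keep])
}

#' Validate a type stratification by holdout reclassification
#'
#' Repeated stratified holdout: in each round a `1 - holdout` fraction of
#' every class trains a linear classifier on the metagene vectors and the
#' held-out samples are reclassified; the returned rate is the mean
#' fraction of held-out samples whose prediction disagrees with the
#' assigned type. Default classifier is a linear support vector machine;
#' `method = "lda"` uses linear discriminant analysis on the leading
#' principal components (rank-reduced to keep the pooled covariance
#' well-conditioned). Rounds whose training split lacks a class are
#' skipped with a warning.
#'
#' @param model A `som_model`.
#' @param labels Character vector of type labels (or a `type_assignment`).
#' @param n_rounds Holdout repetitions (default 10).
#' @param holdout Held-out fraction per class (default 0.3).
#' @param method `"svm"` (linear, default) or `"lda"`.
#' @param seed Integer seed.
#' @return Mean misclassification rate in `[0, 1]`, with the per-round
#'   rates in `attr(, "rounds")`.
#' @export
validate_types <- function(model, labels, n_rounds = 10, holdout = 0.3,
                           method = c("svm", "lda"), seed = 1L) {
  stopifnot(inherits(model, "som_model"))
  method <- match.arg(method)
  if (inherits(labels, "type_assignment")) {
    labels <- labels$type[match(model$sample_ids, labels$sample_id)]
  }
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least two type labels", call. = FALSE)
  X <- t(model$codebook)
  set.seed(seed)
  rates <- rep(NA_real_, n_rounds)
  for (b in seq_len(n_rounds)) {
    test_idx <- unlist(lapply(levels(labels), function(l) {
      idx <- which(labels == l)
      idx[sample.int(length(idx), max(1L, round(holdout * length(idx))))]
    }))
    train_idx <- setdiff(seq_len(nrow(X)), test_idx)
    if (nlevels(droplevels(labels[train_idx])) < nlevels(labels)) {
      warning("round ", b, " skipped: class missing from training split",
              call. = FALSE)
      next
    }
    pred <- switch(method,
      svm = {
        fit <- e1071::svm(x = X[train_idx, , drop = FALSE],
                          y = droplevels(labels[train_idx]),
                          kernel = "linear", scale = FALSE)
        stats::predict(fit, X[test_idx, , drop = FALSE])
      },
      lda = {
        pc <- stats::prcomp(X[train_idx, , drop = FALSE], rank. =
                              min(10L, length(train_idx) - 2L, ncol(X)))
        fit <- MASS::lda(pc$x, grouping = droplevels(labels[train_idx]))
        te <- scale(X[test_idx, , drop = FALSE], center = pc$center,
                    scale = FALSE) %*% pc$rotation
        stats::predict(fit, te)$class
      }
    )
    rates[b] <- mean(as.character(pred) != as.character(labels[test_idx]))
  }
  out <- mean(rates, na.rm = TRUE)
  attr(out, "rounds") <- rates
  out
}

#' One-row summary of a type assignment
#'
#' @param x A `type_assignment`.
#' @param ... Unused.
#' @return Tibble with sample, type and subtype counts.
#' @export
glance.type_assignment <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x),
                 n_types = length(unique(x$type)),
                 n_subtypes = length(unique(x$subtype)))
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same samples;
#' 1 means identical partitions, 0 the expected agreement of random
#' labelings.
#'
#' @param a,b Label vectors of equal length.
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
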