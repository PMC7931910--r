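#' Phenotype-to-metagene correlation map
#'
#' Correlates one phenotype's values over samples with every metagene
#' expression profile, giving a "phenotype portrait" on the map grid.
#' Continuous features use Pearson correlation; binary (0/1) features the
#' point-biserial correlation, computed as Pearson on the indicator coding
#' (a mathematical identity); categorical features expand into one
#' one-vs-rest binary map per level. Samples with a missing feature value
#' are dropped pairwise; zero-variance metagenes correlate 0.
#'
#' @param model A `som_model`.
#' @param phenotypes Tibble with `sample_id` and feature columns (e.g.
#'   from [generate_cohort()] or [read_phenotypes()]).
#' @param feature Feature column name.
#' @return For continuous/binary features an object of class
#'   `correlation_map`: list with `feature`, `grid` (correlations),
#'   `argmax`/`argmin` (row, col of the extreme units), `n_used`. For
#'   categorical features a named list of such maps, one per level.
#' @export
correlation_map <- function(model, phenotypes, feature) {
  stopifnot(inherits(model, "som_model"))
  if (!feature %in% names(phenotypes)) {
    stop("unknown feature: ", feature, call. = FALSE)
  }
  v <- phenotypes[[feature]][match(model$sample_ids, phenotypes$sample_id)]
  if (is.logical(v)) v <- as.integer(v)
  if (is.character(v) || is.factor(v)) {
    lev <- sort(unique(as.character(v[!is.na(v)])))
    maps <- lapply(lev, function(l) {
      correlation_map_numeric(model, as.integer(as.character(v) == l),
                              paste0(feature, "=", l))
    })
    names(maps) <- lev
    return(maps)
  }
  correlation_map_numeric(model, v, feature)
}

correlation_map_numeric <- function(model, v, feature) {
  keep <- !is.na(v)
  if (sum(keep) < 3) stop("need >= 3 samples with non-missing '", feature,
                          "'", call. = FALSE)
  f <- v[keep]
  if (stats::sd(f) == 0) {
    stop("feature '", feature, "' has zero variance", call. = FALSE)
  }
  C <- model$codebook[, keep, drop = FALSE]
  fc <- f - mean(f)
  Cc <- C - rowMeans(C)
  num <- as.vector(Cc %*% fc)
  den <- sqrt(rowSums(Cc^2)) * sqrt(sum(fc^2))
  r <- ifelse(den > 0, num / den, 0)
  grid <- matrix(r, model$grid_rows, model$grid_cols, byrow = TRUE)
  amax <- arrayInd(which.max(grid), dim(grid))
  amin <- arrayInd(which.min(grid), dim(grid))
  structure(list(feature = feature, grid = grid,
                 argmax = c(row = amax[1], col = amax[2]),
                 argmin = c(row = amin[1], col = amin[2]),
                 n_used = sum(keep)),
            class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  cat("Correlation map for", x$feature, "(", nrow(x$grid), "x",
      ncol(x$grid), "); r in", signif(min(x$grid), 3), "..",
      signif(max(x$grid), 3), "; n =", x$n_used, "\n")
  invisible(x)
}

#' Overview of maximum-correlation units across features
#'
#' @param model A `som_model`.
#' @param phenotypes Phenotype tibble.
#' @param features Feature column names (default all non-id columns).
#' @return Tibble (`feature`, `argmax_row`, `argmax_col`, `r_max`,
#'   `r_min`, `n_used`), one row per feature (or per categorical level).
#' @export
phenotype_overview <- function(model, phenotypes,
                               features = setdiff(names(phenotypes),
                                                  "sample_id")) {
  maps <- list()
  for (f in features) {
    m <- correlation_map(model, phenotypes, f)
    if (inherits(m, "correlation_map")) m <- list(m)
    maps <- c(maps, m)
  }
  purrr::map_dfr(maps, function(m) {
    tibble::tibble(feature = m$feature,
                   argmax_row = m$argmax["row"], argmax_col = m$argmax["col"],
                   r_max = max(m$grid), r_min = min(m$grid),
                   n_used = m$n_used)
  })
}

#' Enrichment of categorical phenotypes in transcriptome types
#'
#' For every (type, level) cell, tests over-representation of the level
#' within the type with a one-tailed (right) Fisher's exact test on the
#' 2x2 table (in type / not) x (has level / not), plus Benjamini-Hochberg
#' FDR across cells. Empty margins give p = 1 with a `degenerate` flag.
#'
#' @param assignment A `type_assignment` (or tibble with `sample_id` and
#'   `type`).
#' @param phenotypes Phenotype tibble.
#' @param feature Categorical (or binary) feature column.
#' @param by Grouping column of `assignment` to test (default `"type"`,
#'   use `"subtype"` for subtype enrichment).
#' @return Tibble (`type`, `level`, `n_type`, `n_level`, `overlap`,
#'   `expected`, `direction`, `p`, `fdr`, `degenerate`).
#' @export
type_enrichment <- function(assignment, phenotypes, feature, by = "type") {
  stopifnot(by %in% names(assignment), feature %in% names(phenotypes))
  df <- dplyr::inner_join(
    dplyr::select(assignment, "sample_id", group = dplyr::all_of(by)),
    dplyr::select(phenotypes, "sample_id", value = dplyr::all_of(feature)),
    by = "sample_id"
  )
  df <- df[!is.na(df$value), , drop = FALSE]
  N <- nrow(df)
  groups <- sort(unique(df$group))
  levels <- sort(unique(as.character(df$value)))
  if (length(groups) < 2 || length(levels) < 2) {
    stop("need >= 2 types and >= 2 feature levels", call. = FALSE)
  }
  cells <- tidyr::expand_grid(type = groups, level = levels)
  res <- purrr::pmap_dfr(cells, function(type, level) {
    in_type <- df$group == type
    has_lev <- as.character(df$value) == level
    a <- sum(in_type & has_lev)
    n_t <- sum(in_type); n_l <- sum(has_lev)
    degenerate <- n_t == 0 || n_l == 0 || n_l == N || n_t == N
    p <- if (degenerate) 1 else {
      stats::phyper(a - 1, n_l, N - n_l, n_t, lower.tail = FALSE)
    }
    expected <- n_t * n_l / N
    tibble::tibble(type = type, level = level, n_type = n_t, n_level = n_l,
                   overlap = a, expected = expected,
                   direction = ifelse(a >= expected, "enriched", "depleted"),
                   p = min(1, p), degenerate = degenerate)
  })
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  dplyr::relocate(res, "fdr", .after = "p")
}

#' Standardized multiple regression of spot expression on phenotypes
#'
#' Fits each spot's expression profile by ordinary least squares on the
#' phenotype design, with response and predictors z-scored so the
#' coefficients are standardized effect sizes; categorical phenotypes
#' expand into one-vs-rest indicators. Collinear columns are dropped with
#' a warning (reported in `attr(, "dropped")`). Per-coefficient p-values
#' are the usual t-tests; FDR is Benjamini-Hochberg across all
#' (spot, phenotype) cells.
#'
#' @param spots A `spot_set`.
#' @param phenotypes Phenotype tibble.
#' @param features Phenotype columns to use (default all non-id columns).
#' @return Tibble (`spot_id`, `term`, `beta_std`, `p`, `fdr`).
#' @export
spot_regression <- function(spots, phenotypes,
                            features = setdiff(names(phenotypes),
                                               "sample_id")) {
  stopifnot(inherits(spots, "spot_set"))
  prof <- attr(spots, "profiles")
  ph <- phenotypes[match(colnames(prof), phenotypes$sample_id), ,
                   drop = FALSE]
  X <- list()
  for (f in features) {
    v <- ph[[f]]
    if (is.character(v) || is.factor(v)) {
      for (l in sort(unique(as.character(v[!is.na(v)])))) {
        X[[paste0(f, "=", l)]] <- as.numeric(as.character(v) == l)
      }
    } else {
      X[[f]] <- as.numeric(v)
    }
  }
  X <- do.call(cbind, X)
  keep <- stats::complete.cases(X)
  X <- scale(X[keep, , drop = FALSE])
  constant <- apply(X, 2, function(col) anyNA(col))
  if (any(constant)) {
    warning("dropping zero-variance columns: ",
            paste(colnames(X)[constant], collapse = ", "), call. = FALSE)
    X <- X[, !constant, drop = FALSE]
  }
  qrX <- qr(cbind(1, X))
  dropped <- character(0)
  if (qrX$rank < ncol(X) + 1) {
    keep_cols <- setdiff(qrX$pivot[seq_len(qrX$rank)], 1L) - 1L
    dropped <- setdiff(colnames(X), colnames(X)[keep_cols])
    warning("dropping collinear columns: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    X <- X[, keep_cols, drop = FALSE]
  }
  res <- purrr::map_dfr(rownames(prof), function(sp) {
    y <- as.vector(scale(prof[sp, keep]))
    fit <- stats::lm(y ~ X)
    co <- summary(fit)$coefficients
    terms <- sub("^X", "", rownames(co))
    ok <- terms != "(Intercept)"
    tibble::tibble(spot_id = sp, term = terms[ok],
                   beta_std = co[ok, "Estimate"],
                   p = co[ok, "Pr(>|t|)"])
  })
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  attr(res, "dropped") <- dropped
  res
}

#' LOESS trend of a response against a covariate
#'
#' Tricube-weighted local linear regression (`stats::loess`, degree 1)
#' evaluated on `n_grid` evenly spaced covariate values, optionally per
#' group (e.g. separate curves for women and men). Spans too small to
#' hold a local neighborhood are widened with a warning.
#'
#' @param data Data frame.
#' @param x,y Column names (strings) of the covariate and response.
#' @param group Optional grouping column name.
#' @param span LOESS span (default 0.5).
#' @param n_grid Number of evaluation points (default 100).
#' @return Tibble (`group`, `x`, `fitted`) — `group` is `"all"` when no
#'   grouping is given.
#' @export
loess_trend <- function(data, x, y, group = NULL, span = 0.5, n_grid = 100) {
  stopifnot(x %in% names(data), y %in% names(data))
  df <- data.frame(x = data[[x]], y = data[[y]],
                   g = if (is.null(group)) "all" else as.character(data[[group]]))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  purrr::map_dfr(split(df, df$g), function(d) {
    if (nrow(d) < 10) {
      stop("need >= 10 points per group for a LOESS fit", call. = FALSE)
    }
    sp <- span
    if (sp * nrow(d) < 5) {
      sp <- min(1, 5 / nrow(d))
      warning("span widened to ", signif(sp, 3),
              " to cover a local neighborhood", call. = FALSE)
    }
    fit <- stats::loess(y ~ x, data = d, span = sp, degree = 1,
                        family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    gx <- seq(min(d$x), max(d$x), length.out = n_grid)
    fitted <- unname(stats::predict(fit, newdata = data.frame(x = gx)))
    tibble::tibble(group = d$g[1], x = gx, fitted = fitted)
  })
}
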