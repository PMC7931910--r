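#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto the common distribution given by the
#' across-sample mean of order statistics; tied values within a column
#' receive the mean of the order-statistic means they span. Gene and sample
#' identifiers are preserved. Delegates to
#' \code{limma::normalizeQuantiles(ties = TRUE)}.
#'
#' @param x Numeric matrix, genes x samples, no missing values.
#' @return Matrix of the same shape and dimnames.
#' @export
#' @examples
#' quantile_normalize(cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("quantile normalization needs >= 2 samples", call. = FALSE)
  if (anyNA(x)) {
    stop("missing values present; impute or remove them before ",
         "quantile normalization", call. = FALSE)
  }
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Center each gene to mean zero
#'
#' Subtracts the row (gene) mean from every expression value, the
#' "centralization" step applied before map training so that portraits show
#' expression relative to the cohort average.
#'
#' @param x Numeric matrix, genes x samples.
#' @return Matrix with every row mean 0 and attribute `centered = TRUE`.
#' @export
center_genes <- function(x) {
  x <- as.matrix(x)
  out <- x - rowMeans(x)
  attr(out, "centered") <- TRUE
  out
}

#' Shifted log2 transform for raw intensities
#'
#' Convenience for inputs not already on log scale: `log2(x + offset)`.
#'
#' @param x Non-negative numeric matrix.
#' @param offset Pseudo-count added before the log (default 1).
#' @return Transformed matrix.
#' @export
log2_transform <- function(x, offset = 1) {
  x <- as.matrix(x)
  if (any(x + offset <= 0)) stop("values must exceed -offset", call. = FALSE)
  log2(x + offset)
}

#' Standard preprocessing: quantile normalization then gene centering
#'
#' @param x Numeric matrix, genes x samples (log2 scale).
#' @param log2 If `TRUE`, apply [log2_transform()] first.
#' @return Preprocessed matrix (centered).
#' @export
preprocess_expression <- function(x, log2 = FALSE) {
  if (log2) x <- log2_transform(x)
  center_genes(quantile_normalize(x))
}
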