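#' Median-of-ratios size factors
#'
#' Per-sample normalisation factors computed as the median, over genes
#' expressed in every sample, of the ratio of the sample's count to the
#' gene's geometric mean across samples (the standard RNA-seq
#' median-of-ratios estimator).
#'
#' @param counts non-negative count matrix, genes x samples.
#' @return Named positive numeric vector, one factor per sample.
#' @examples
#' m <- rbind(c(10, 20), c(100, 200))
#' size_factors(m)  # 1/sqrt(2), sqrt(2)
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  logs <- log(counts)
  loggeo <- rowMeans(logs)
  use <- is.finite(loggeo)
  if (!any(use)) {
    stop("no gene has nonzero counts in all samples; size factors undefined",
         call. = FALSE)
  }
  sf <- apply(logs[use, , drop = FALSE], 2,
              function(col) exp(stats::median(col - loggeo[use])))
  stats::setNames(sf, colnames(counts))
}

#' Simplified variance-stabilising transform
#'
#' `log2(count / size factor + 1)`, element-wise: a monotone transform that
#' flattens the NB mean-variance relation at moderate means. This is a
#' declared simplification of package VSTs, exposed as the package's
#' clustering input.
#'
#' @param counts count matrix, genes x samples.
#' @param factors per-sample positive size factors (default:
#'   [size_factors()]).
#' @return Numeric matrix of stabilised values.
#' @export
vst_counts <- function(counts, factors = size_factors(counts)) {
  counts <- as.matrix(counts)
  if (length(factors) != ncol(counts) || any(factors <= 0)) {
    stop("`factors` must be one positive value per sample", call. = FALSE)
  }
  log2(sweep(counts, 2, factors, `/`) + 1)
}

#' Mean-centre each gene
#'
#' Subtracts the row mean from every row, the per-gene centring applied
#' before clustering. Idempotent.
#'
#' @param x numeric matrix with >= 1 column.
#' @return Matrix with row means 0 (to numeric tolerance).
#' @export
center_rows <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 1L) stop("need at least one column", call. = FALSE)
  sweep(x, 1, rowMeans(x), `-`)
}
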