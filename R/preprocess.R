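# Count preprocessing: median-of-ratios size factors, a shifted-log
# variance-stabilizing transform, and low-expression filtering. Downstream
# statistics are rank-based (Spearman), so any strictly monotone per-sample
# transform yields identical correlation matrices; the shifted log is chosen
# for the eigengene step, the one place the transform's shape matters.

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: for each sample, the median over genes
#' (restricted to genes with a positive count in every sample) of the ratio
#' of the gene's count to the gene's geometric mean across samples.
#'
#' @param counts A [coex_counts()] object.
#' @return Named positive numeric vector, one factor per sample.
#' @examples
#' m <- matrix(c(2, 8, 4, 16), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' # geometric-mean reference makes the factors (1/sqrt(2), sqrt(2))
#' @export
estimate_size_factors <- function(counts) {
  stopifnot(inherits(counts, "coex_counts"))
  loggeo <- rowMeans(log(counts$counts))
  usable <- is.finite(loggeo)  # genes with positive count in every sample
  if (!any(usable))
    stop("size factors undefined: no gene has a nonzero count in every sample")
  sf <- apply(counts$counts[usable, , drop = FALSE], 2L, function(col)
    exp(median(log(col) - loggeo[usable])))
  setNames(sf, colnames(counts$counts))
}

#' Shifted-log variance-stabilizing transform
#'
#' `log2(count / size_factor + 1)` per cell. Strictly monotone within each
#' sample, so every Spearman-derived statistic downstream is invariant to
#' the choice of log base or pseudocount.
#'
#' @param counts A [coex_counts()] object.
#' @param size_factors Positive numeric vector per sample; estimated with
#'   [estimate_size_factors()] when omitted.
#' @return A [coex_expr()] object on the transformed scale.
#' @export
vst_transform <- function(counts, size_factors = NULL) {
  stopifnot(inherits(counts, "coex_counts"))
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  if (length(size_factors) != ncol(counts$counts))
    stop("size_factors length must equal the number of samples")
  if (any(size_factors <= 0)) stop("size factors must be positive")
  v <- log2(sweep(counts$counts, 2L, size_factors, "/") + 1)
  coex_expr(v, counts$samples)
}

#' Filter low-expression genes
#'
#' Retains genes whose raw count is at least `min_count` in at least
#' `min_samples` samples. Gene order is preserved. The retained-gene report
#' is attached as attribute `"filter_report"`.
#'
#' @param counts A [coex_counts()] object.
#' @param min_count Minimum count a sample must reach to support a gene
#'   (default 5).
#' @param min_samples Number of supporting samples required; default 25% of
#'   samples (rounded up).
#' @return Filtered [coex_counts()]; `attr(, "filter_report")` is a
#'   `data.frame` with `gene_id`, `n_supporting`, `retained`.
#' @export
filter_genes <- function(counts, min_count = 5,
                         min_samples = ceiling(0.25 * ncol(counts$counts))) {
  stopifnot(inherits(counts, "coex_counts"))
  if (min_count < 0 || min_samples < 0) stop("thresholds must be >= 0")
  if (min_samples > ncol(counts$counts))
    stop("min_samples exceeds the number of samples (",
         ncol(counts$counts), ")")
  n_support <- rowSums(counts$counts >= min_count)
  keep <- n_support >= min_samples
  if (!any(keep)) stop("no genes pass the filter")
  report <- data.frame(gene_id = rownames(counts$counts),
                       n_supporting = n_support,
                       retained = keep, row.names = NULL)
  out <- coex_counts(counts$counts[keep, , drop = FALSE], counts$samples)
  attr(out, "filter_report") <- report
  out
}
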