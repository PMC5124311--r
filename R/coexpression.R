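# Condition-wise Spearman correlation, signed squared adjacency, the
# between-condition difference dissimilarity, the topological overlap matrix
# of that dissimilarity, and the transcriptome-wide coexpression index with
# its distribution comparisons. All matrices are plain symmetric gene x gene
# matrices carrying gene ids as dimnames.

#' Spearman rank-correlation matrix for one condition
#'
#' Computes the gene x gene Spearman correlation across the samples of one
#' condition: per-gene average-rank transform followed by Pearson correlation
#' of ranks (ties receive average ranks). Genes that are constant within the
#' condition have zero rank variance; their correlations are set to 0 and a
#' warning reports how many genes were affected.
#'
#' @param expr A [coex_expr()] object.
#' @param condition One of the two condition labels in `expr$samples`.
#' @return Symmetric numeric matrix with unit diagonal and attribute
#'   `"condition"`.
#' @export
spearman_matrix <- function(expr, condition) {
  stopifnot(inherits(expr, "coex_expr"))
  cols <- condition_columns(expr, condition)
  if (length(cols) < 3L) stop("condition '", condition, "' has < 3 samples")
  x <- expr$values[, cols, drop = FALSE]
  const <- apply(x, 1L, function(v) max(v) == min(v))
  rho <- suppressWarnings(cor(t(x), method = "spearman"))
  if (any(const)) {
    warning(sum(const), " constant gene(s) in condition '", condition,
            "' assigned zero correlation")
    rho[const, ] <- 0
    rho[, const] <- 0
  }
  rho[is.na(rho)] <- 0
  diag(rho) <- 1
  attr(rho, "condition") <- condition
  rho
}

#' Signed squared adjacency
#'
#' `a_ij = sign(rho_ij) * rho_ij^2`: the per-condition edge weight that keeps
#' the correlation's sign while squaring its magnitude.
#'
#' @param corr Symmetric correlation matrix (values in `[-1, 1]`).
#' @return Matrix of the same shape with attribute `"condition"` preserved.
#' @export
signed_adjacency <- function(corr) {
  check_symmetric(corr, lo = -1, hi = 1)
  a <- sign(corr) * corr^2
  attr(a, "condition") <- attr(corr, "condition")
  a
}

#' Between-condition adjacency-difference dissimilarity
#'
#' `d_ij = (sqrt(0.5 * |a1_ij - a2_ij|))^beta`, the dissimilarity that
#' quantifies how much the signed coexpression of a gene pair changes
#' between conditions; 0 = no change, 1 = full sign reversal of perfect
#' correlation. The diagonal is forced to 0.
#'
#' @param a1,a2 Signed adjacency matrices over the same genes.
#' @param beta Positive soft-threshold exponent (default 1; no soft power is
#'   applied beyond the squaring already inside the adjacency).
#' @return Symmetric matrix in `[0, 1]` with zero diagonal and attribute
#'   `"beta"`.
#' @export
difference_dissimilarity <- function(a1, a2, beta = 1) {
  if (!identical(dimnames(a1), dimnames(a2)))
    stop("adjacency matrices have mismatched gene ids")
  if (beta <= 0) stop("beta must be positive")
  d <- (sqrt(0.5 * abs(a1 - a2)))^beta
  diag(d) <- 0
  attr(d, "condition") <- NULL
  attr(d, "beta") <- beta
  d
}

#' Topological overlap of the difference dissimilarity
#'
#' Standard unsigned topological overlap applied to the change matrix `d`:
#' `T_ij = (l_ij + d_ij) / (min(k_i, k_j) + 1 - d_ij)` with
#' `l_ij = sum_{u != i,j} d_iu d_uj` and connectivity `k_i = sum_{u != i}
#' d_iu`. Pairs whose coexpression change is shared by many common
#' neighbours score high; `1 - T` is the clustering dissimilarity.
#'
#' @param d Difference dissimilarity matrix (symmetric, in `[0, 1]`, zero
#'   diagonal).
#' @return Symmetric matrix in `[0, 1]` with unit diagonal.
#' @export
topological_overlap <- function(d) {
  check_symmetric(d, lo = 0, hi = 1)
  if (any(diag(d) != 0)) stop("dissimilarity diagonal must be zero")
  l <- d %*% d            # diagonal of d is zero, so u = i, j contribute 0
  k <- rowSums(d)
  kmin <- outer(k, k, pmin)
  tom <- (l + d) / (kmin + 1 - d)
  tom[kmin + 1 - d == 0] <- 0   # isolated pair of genes: no overlap
  tom <- pmin(pmax(tom, 0), 1)  # guard rounding at the boundaries
  diag(tom) <- 1
  dimnames(tom) <- dimnames(d)
  tom
}

#' Coexpression index per gene pair
#'
#' The unsigned squared Spearman correlation `rho^2` for every unordered
#' off-diagonal gene pair: 0 = no co-regulation, 1 = perfect co-regulation
#' irrespective of sign.
#'
#' @param corr Spearman correlation matrix from [spearman_matrix()].
#' @return Numeric vector of length `n (n - 1) / 2` (upper triangle order),
#'   with attribute `"condition"`.
#' @export
coexpression_index <- function(corr) {
  check_symmetric(corr, lo = -1, hi = 1)
  idx <- corr[upper.tri(corr)]^2
  attr(idx, "condition") <- attr(corr, "condition")
  idx
}

#' Compare transcriptome-wide coexpression-index distributions
#'
#' Two-sample Kolmogorov-Smirnov and Wilcoxon rank-sum comparisons of the
#' per-pair coexpression index between conditions. When the number of pairs
#' exceeds `max_pairs`, the same seeded uniform subsample of pairs is used in
#' both conditions.
#'
#' @param idx_a,idx_b Coexpression-index vectors over the same gene pairs
#'   (from [coexpression_index()]).
#' @param max_pairs Largest number of pairs tested without subsampling
#'   (default 2e6).
#' @param seed Integer seed for the pair subsample.
#' @return A `dist_comparison` list: `ks_statistic`, `ks_p`, `rank_sum_W`,
#'   `rank_sum_p`, `medians` (named per condition), `direction`, `n_pairs`,
#'   `subsampled`, `seed`.
#' @export
compare_distributions <- function(idx_a, idx_b, max_pairs = 2e6, seed = 1L) {
  if (length(idx_a) == 0L || length(idx_b) == 0L)
    stop("empty coexpression-index set")
  if (length(idx_a) != length(idx_b))
    stop("index sets must cover the same gene pairs")
  lab_a <- attr(idx_a, "condition") %||% "A"
  lab_b <- attr(idx_b, "condition") %||% "B"
  subsampled <- length(idx_a) > max_pairs
  if (subsampled) {
    set.seed(seed)
    pick <- sample.int(length(idx_a), max_pairs)
    idx_a <- idx_a[pick]
    idx_b <- idx_b[pick]
  }
  ks <- suppressWarnings(ks.test(idx_a, idx_b))
  w <- suppressWarnings(wilcox.test(idx_a, idx_b))
  med <- setNames(c(median(idx_a), median(idx_b)), c(lab_a, lab_b))
  dir <- if (med[1] > med[2]) paste(lab_a, ">", lab_b)
         else if (med[1] < med[2]) paste(lab_a, "<", lab_b)
         else "equal medians"
  structure(list(ks_statistic = unname(ks$statistic),
                 ks_p = ks$p.value,
                 rank_sum_W = unname(w$statistic),
                 rank_sum_p = w$p.value,
                 medians = med,
                 direction = dir,
                 n_pairs = length(idx_a),
                 subsampled = subsampled,
                 seed = if (subsampled) seed else NA_integer_),
            class = "dist_comparison")
}

#' @export
print.dist_comparison <- function(x, ...) {
  cat("Coexpression-index distribution comparison (", x$n_pairs, " pairs",
      if (x$subsampled) ", subsampled" else "", ")\n", sep = "")
  cat(sprintf("  KS D = %.4g (p = %.3g)\n", x$ks_statistic, x$ks_p))
  cat(sprintf("  rank-sum W = %.4g (p = %.3g)\n", x$rank_sum_W, x$rank_sum_p))
  cat(sprintf("  medians: %s = %.4g, %s = %.4g (%s)\n",
              names(x$medians)[1], x$medians[1],
              names(x$medians)[2], x$medians[2], x$direction))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_symmetric <- function(m, lo, hi, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("matrix must be square")
  if (max(abs(m - t(m))) > tol) stop("matrix must be symmetric")
  if (min(m) < lo - tol || max(m) > hi + tol)
    stop("matrix values outside [", lo, ", ", hi, "]")
  invisible(TRUE)
}
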