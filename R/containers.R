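# Lightweight S3 containers. Matrices are plain base-R matrices with gene ids
# as rownames and sample ids as colnames; sample annotations travel alongside
# in a data.frame, following the convention of coexpression-network packages.

#' Count matrix with sample annotations
#'
#' Bundles a non-negative integer gene x sample count matrix with a sample
#' metadata table giving, for every sample, the experimental condition
#' (exactly two levels) and the genetic line it came from.
#'
#' @param counts Non-negative numeric matrix, genes in rows, samples in
#'   columns; must have row and column names.
#' @param samples `data.frame` with columns `sample_id`, `condition`, `line`;
#'   `sample_id` must match `colnames(counts)` in order.
#' @return An object of class `coex_counts`: a list with elements `counts`
#'   and `samples`.
#' @examples
#' m <- matrix(rpois(12, 10), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' meta <- data.frame(sample_id = colnames(m),
#'                    condition = rep(c("A", "B"), each = 2),
#'                    line = rep(1:2, 2))
#' coex_counts(m, meta)
#' @export
coex_counts <- function(counts, samples) {
  counts <- as.matrix(counts)
  check_sample_table(counts, samples, "counts")
  if (anyNA(counts)) stop("count matrix contains missing values")
  if (any(counts < 0)) stop("count matrix contains negative values")
  structure(list(counts = counts, samples = samples), class = "coex_counts")
}

#' Expression matrix with sample annotations
#'
#' Holds variance-stabilized (or otherwise transformed) gene x sample
#' expression values plus the same sample annotations as the source counts.
#' This is the substrate for all rank-correlation computations.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   dimnames; all values must be finite.
#' @inheritParams coex_counts
#' @return An object of class `coex_expr`: a list with elements `values`
#'   and `samples`.
#' @export
coex_expr <- function(values, samples) {
  values <- as.matrix(values)
  check_sample_table(values, samples, "values")
  if (!all(is.finite(values))) stop("expression matrix contains non-finite values")
  structure(list(values = values, samples = samples), class = "coex_expr")
}

check_sample_table <- function(mat, samples, what) {
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop(what, " matrix must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(mat)))
    stop("duplicate gene ids in ", what, " matrix: ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", "))
  req <- c("sample_id", "condition", "line")
  if (!is.data.frame(samples) || !all(req %in% names(samples)))
    stop("samples must be a data.frame with columns ",
         paste(req, collapse = ", "))
  if (!identical(as.character(samples$sample_id), colnames(mat)))
    stop("samples$sample_id must match matrix column names in order")
  conds <- unique(as.character(samples$condition))
  if (length(conds) != 2L)
    stop("exactly two condition levels required, found ", length(conds))
  tab <- table(samples$condition)
  if (any(tab < 3L))
    stop("each condition needs >= 3 samples; ",
         names(tab)[which.min(tab)], " has ", min(tab))
  invisible(TRUE)
}

#' @export
print.coex_counts <- function(x, ...) {
  cat("coex_counts: ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples\n", sep = "")
  cat("conditions: ", paste(names(table(x$samples$condition)),
      table(x$samples$condition), sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.coex_expr <- function(x, ...) {
  cat("coex_expr: ", nrow(x$values), " genes x ", ncol(x$values),
      " samples\n", sep = "")
  cat("conditions: ", paste(names(table(x$samples$condition)),
      table(x$samples$condition), sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Condition levels of an annotated matrix
#'
#' @param x A `coex_counts` or `coex_expr` object.
#' @return Character vector of the two condition labels, in order of first
#'   appearance in the sample table.
#' @export
conditions_of <- function(x) {
  unique(as.character(x$samples$condition))
}

# Column indices of the samples in one condition, with validation.
condition_columns <- function(x, condition) {
  cond <- as.character(x$samples$condition)
  if (!condition %in% cond)
    stop("condition '", condition, "' absent from sample metadata (levels: ",
         paste(unique(cond), collapse = ", "), ")")
  which(cond == condition)
}

#' Subset genes of an annotated matrix
#'
#' @param x A `coex_counts` or `coex_expr` object.
#' @param genes Character vector of gene ids (or logical/integer index).
#' @return Object of the same class restricted to `genes`, order preserved.
#' @export
subset_genes <- function(x, genes) {
  if (inherits(x, "coex_counts")) {
    coex_counts(x$counts[genes, , drop = FALSE], x$samples)
  } else if (inherits(x, "coex_expr")) {
    coex_expr(x$values[genes, , drop = FALSE], x$samples)
  } else stop("unsupported class")
}
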