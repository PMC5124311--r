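# Module detection: average-linkage clustering of genes on 1 - TOM, a static
# height cut with minimum-size dissolution (a simplified variant of the
# hybrid dynamic tree cut: the static parameters are kept, the PAM-like
# reassignment stage is a documented extension point), module eigengenes as
# first principal components, and eigengene-based module merging.

#' Cluster genes on the topological overlap
#'
#' Average-linkage hierarchical clustering with dissimilarity `1 - TOM`.
#'
#' @param tom Topological overlap matrix from [topological_overlap()].
#' @return An [stats::hclust] dendrogram (method `"average"`).
#' @export
cluster_genes <- function(tom) {
  if (!is.matrix(tom) || nrow(tom) != ncol(tom)) stop("TOM must be square")
  hclust(as.dist(1 - tom), method = "average")
}

#' Cut the gene dendrogram into modules
#'
#' Static cut at `min_height + height_fraction * (max_height - min_height)`
#' over the dendrogram's merge heights; branches with fewer than `min_size`
#' leaves are dissolved to module 0 (unassigned). Remaining modules are
#' labeled 1, 2, ... by decreasing size (ties broken by lowest gene index).
#'
#' @param dendro An [stats::hclust] object from [cluster_genes()].
#' @param height_fraction Cut position as a fraction of the tree's height
#'   range, in `(0, 1)`; default 0.712 (a cut height of 0.79 on a tree whose
#'   heights span 71.2% of range at 0.79).
#' @param min_size Minimum module size (>= 2); default 100.
#' @return A `module_assignment` list: `modules` (named integer vector,
#'   0 = unassigned), `sizes` (named by label), `params`.
#' @export
cut_tree <- function(dendro, height_fraction = 0.712, min_size = 100) {
  stopifnot(inherits(dendro, "hclust"))
  if (height_fraction <= 0 || height_fraction >= 1)
    stop("height_fraction must be in (0, 1)")
  if (min_size < 1) stop("min_size must be >= 1")
  h <- min(dendro$height) +
    height_fraction * (max(dendro$height) - min(dendro$height))
  raw <- cutree(dendro, h = h)
  new_assignment(raw, min_size,
                 params = list(height_fraction = height_fraction,
                               cut_height = h, min_size = min_size))
}

# Dissolve undersized clusters and relabel survivors by decreasing size
# (ties by first gene index); returns a module_assignment.
new_assignment <- function(raw, min_size, params) {
  sizes <- table(raw)
  keep_labels <- setdiff(names(sizes)[sizes >= min_size], "0")
  modules <- integer(length(raw))
  names(modules) <- names(raw)
  if (length(keep_labels) > 0) {
    first_idx <- vapply(keep_labels,
                        function(l) which(raw == l)[1L], integer(1))
    ord <- keep_labels[order(-as.integer(sizes[keep_labels]), first_idx)]
    for (i in seq_along(ord)) modules[raw == ord[i]] <- i
  }
  out_sizes <- table(modules[modules > 0])
  structure(list(modules = modules,
                 sizes = setNames(as.integer(out_sizes), names(out_sizes)),
                 params = params),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  n_mod <- length(x$sizes)
  cat("module_assignment: ", n_mod, " module(s), ",
      sum(x$modules > 0), "/", length(x$modules), " genes assigned\n", sep = "")
  if (n_mod > 0) print(x$sizes)
  invisible(x)
}

#' Genes of one module
#' @param assignment A `module_assignment`.
#' @param module Integer module label (> 0).
#' @return Character vector of gene ids.
#' @export
module_genes <- function(assignment, module) {
  g <- names(assignment$modules)[assignment$modules == module]
  if (length(g) == 0) stop("module ", module, " not present in assignment")
  g
}

#' Module eigengenes
#'
#' Per module: member genes are centered and scaled to unit variance across
#' samples, and the first principal component score vector over samples is
#' extracted (the eigengene), normalized to unit length and sign-aligned so
#' that it correlates non-negatively with the module's mean expression
#' profile.
#'
#' @param expr A [coex_expr()] object covering all assigned genes.
#' @param assignment A `module_assignment` with >= 1 module of >= 2 genes.
#' @return Numeric matrix, modules x samples, rownames `ME1`, `ME2`, ...;
#'   attribute `"var_explained"` gives the first component's share of
#'   variance per module.
#' @export
module_eigengene <- function(expr, assignment) {
  stopifnot(inherits(expr, "coex_expr"))
  labels <- sort(unique(assignment$modules[assignment$modules > 0]))
  if (length(labels) == 0) stop("assignment contains no modules")
  n_s <- ncol(expr$values)
  eig <- matrix(0, length(labels), n_s,
                dimnames = list(paste0("ME", labels), colnames(expr$values)))
  varexp <- setNames(numeric(length(labels)), rownames(eig))
  for (i in seq_along(labels)) {
    genes <- module_genes(assignment, labels[i])
    x <- expr$values[genes, , drop = FALSE]
    sds <- apply(x, 1L, sd)
    if (any(sds == 0))
      stop("module ", labels[i], " contains zero-variance gene(s): ",
           paste(head(genes[sds == 0], 3), collapse = ", "))
    xs <- (x - rowMeans(x)) / sds
    sv <- svd(xs)
    e <- sv$v[, 1L]                      # unit-norm score vector over samples
    ref <- colMeans(xs)
    if (sd(ref) == 0) ref <- xs[1L, ]    # mean cancels (e.g. antisymmetric
    if (cor(e, ref) < 0) e <- -e         # pair): align with the first gene
    eig[i, ] <- e
    varexp[i] <- sv$d[1L]^2 / sum(sv$d^2)
  }
  attr(eig, "var_explained") <- varexp
  eig
}

#' Merge modules with similar eigengenes
#'
#' Average-linkage clustering of module eigengenes (unit-norm rows) on
#' Euclidean distance; groups of modules whose eigengenes merge at or below
#' `merge_height` are unioned. Eigengenes of merged modules are recomputed
#' and merging is repeated until no further merges occur, so the operation
#' is idempotent. Labels are recomputed by decreasing size.
#'
#' @param expr A [coex_expr()] object (needed to recompute eigengenes).
#' @param assignment A `module_assignment`.
#' @param merge_height Euclidean-distance threshold at or below which
#'   eigengenes are considered the same module (default 0.2).
#' @return A `module_assignment` with merged, relabeled modules; `params`
#'   records the merge height and the number of merge passes.
#' @export
merge_similar_modules <- function(expr, assignment, merge_height = 0.2) {
  if (merge_height < 0) stop("merge_height must be >= 0")
  modules <- assignment$modules
  passes <- 0L
  repeat {
    labels <- sort(unique(modules[modules > 0]))
    if (length(labels) <= 1L) break
    cur <- structure(list(modules = modules, sizes = NULL, params = NULL),
                     class = "module_assignment")
    eig <- module_eigengene(expr, cur)
    hc <- hclust(dist(eig), method = "average")
    grp <- cutree(hc, h = merge_height)
    if (max(grp) == length(labels)) break  # nothing within merge_height
    passes <- passes + 1L
    remap <- setNames(grp, labels)
    modules[modules > 0] <- unname(remap[as.character(modules[modules > 0])])
  }
  params <- c(assignment$params,
              list(merge_height = merge_height, merge_passes = passes))
  out <- new_assignment(modules, min_size = 1L, params = params)
  out$params <- params
  out
}

#' Mean expression profile per module
#'
#' Arithmetic mean of member genes' expression per sample, with per-condition
#' means attached.
#'
#' @param expr A [coex_expr()] object.
#' @param assignment A `module_assignment`.
#' @return Numeric matrix, modules x samples; attribute
#'   `"condition_means"` holds a modules x 2 matrix of per-condition means.
#' @export
module_mean_expression <- function(expr, assignment) {
  stopifnot(inherits(expr, "coex_expr"))
  labels <- sort(unique(assignment$modules[assignment$modules > 0]))
  if (length(labels) == 0) stop("assignment contains no modules")
  out <- t(vapply(labels, function(l) {
    colMeans(expr$values[module_genes(assignment, l), , drop = FALSE])
  }, numeric(ncol(expr$values))))
  rownames(out) <- paste0("M", labels)
  conds <- conditions_of(expr)
  cm <- vapply(conds, function(cc)
    rowMeans(out[, condition_columns(expr, cc), drop = FALSE]),
    numeric(nrow(out)))
  cm <- matrix(cm, nrow = nrow(out), dimnames = list(rownames(out), conds))
  attr(out, "condition_means") <- cm
  out
}
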