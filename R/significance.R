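# Permutation tests for within-module and between-module differential
# coexpression. The test statistic is the root-mean-square of the
# adjacency-difference dissimilarity d over a module's (or module pair's)
# gene pairs; the null is built by shuffling sample-to-condition labels
# (whole samples, group sizes preserved) and recomputing d restricted to
# the assigned genes. Module assignment is held fixed across permutations:
# the test asks whether coexpression changed within fixed gene sets.

#' Dispersion statistic of a gene set or set pair
#'
#' Root-mean-square of the difference dissimilarity over the unordered
#' within-set pairs (`genes_b` absent) or over all cross pairs between two
#' disjoint sets (`genes_b` present).
#'
#' @param d Difference dissimilarity matrix from
#'   [difference_dissimilarity()].
#' @param genes_a Character vector of gene ids (>= 2 for within mode).
#' @param genes_b Optional second gene set, disjoint from `genes_a`.
#' @return Non-negative scalar in `[0, 1]`.
#' @export
dispersion_statistic <- function(d, genes_a, genes_b = NULL) {
  if (is.null(genes_b)) {
    if (length(genes_a) < 2L) stop("within-set dispersion needs >= 2 genes")
    sub <- d[genes_a, genes_a]
    sqrt(mean(sub[upper.tri(sub)]^2))
  } else {
    if (length(genes_a) == 0L || length(genes_b) == 0L)
      stop("both gene sets must be non-empty")
    if (length(intersect(genes_a, genes_b)) > 0L)
      stop("gene sets overlap in between-set mode")
    sqrt(mean(d[genes_a, genes_b]^2))
  }
}

# d matrix over a gene subset for a given assignment of columns to the two
# conditions (cols_a / cols_b are column indices into expr$values).
diff_dissim_for_split <- function(values, cols_a, cols_b, beta) {
  rho_a <- suppressWarnings(cor(t(values[, cols_a, drop = FALSE]),
                                method = "spearman"))
  rho_b <- suppressWarnings(cor(t(values[, cols_b, drop = FALSE]),
                                method = "spearman"))
  rho_a[is.na(rho_a)] <- 0
  rho_b[is.na(rho_b)] <- 0
  d <- (sqrt(0.5 * abs(sign(rho_a) * rho_a^2 - sign(rho_b) * rho_b^2)))^beta
  diag(d) <- 0
  d
}

#' Permutation test for differential coexpression
#'
#' For each module (and, by default, each module pair), compares the
#' observed dispersion statistic with its distribution under `B` random
#' reassignments of samples to conditions. Empirical p-values follow
#' `p = (1 + #\{null >= observed\}) / (B + 1)`, so `p` lies in
#' `[1/(B+1), 1]` and the observed statistic is counted once.
#' Benjamini-Hochberg adjustment is applied separately across the
#' within-module family and the between-pair family.
#'
#' @param expr A [coex_expr()] object.
#' @param assignment A `module_assignment` with >= 1 module.
#' @param B Number of permutations (default 1000).
#' @param alpha Significance level for DC flags on adjusted p-values
#'   (default 0.05).
#' @param beta Soft-threshold exponent passed to the dissimilarity
#'   (default 1).
#' @param between `"all"` to test every module pair, `"none"` to skip
#'   between-module tests, or a 2-column matrix/data.frame of module label
#'   pairs.
#' @param paired When `TRUE`, permutations swap condition labels within each
#'   line (paired design) instead of freely reassigning samples.
#' @param seed Integer seed for the permutations.
#' @return A `dc_report` list: `within` and `between` data.frames (statistic,
#'   raw and BH-adjusted p, `dc` flag), `null_within` / `null_between`
#'   matrices (B x tests), and the run parameters.
#' @export
permutation_test <- function(expr, assignment, B = 1000, alpha = 0.05,
                             beta = 1, between = "all", paired = FALSE,
                             seed = 1L) {
  stopifnot(inherits(expr, "coex_expr"))
  if (B < 1) stop("B must be >= 1")
  labels <- sort(unique(assignment$modules[assignment$modules > 0]))
  if (length(labels) == 0) stop("assignment contains no modules")
  conds <- conditions_of(expr)
  cols_a <- condition_columns(expr, conds[1])
  cols_b <- condition_columns(expr, conds[2])

  gene_sets <- lapply(labels, function(l) module_genes(assignment, l))
  names(gene_sets) <- as.character(labels)
  assigned <- unlist(gene_sets, use.names = FALSE)
  values <- expr$values[assigned, , drop = FALSE]

  pairs <- resolve_pairs(between, labels)

  stat_all <- function(ca, cb) {
    d <- diff_dissim_for_split(values, ca, cb, beta)
    w <- vapply(gene_sets, function(g) dispersion_statistic(d, g), numeric(1))
    b <- if (nrow(pairs) > 0) {
      vapply(seq_len(nrow(pairs)), function(i)
        dispersion_statistic(d, gene_sets[[as.character(pairs[i, 1])]],
                             gene_sets[[as.character(pairs[i, 2])]]),
        numeric(1))
    } else numeric(0)
    list(within = w, between = b)
  }

  obs <- stat_all(cols_a, cols_b)
  set.seed(seed)
  n_a <- length(cols_a)
  all_cols <- c(cols_a, cols_b)
  null_w <- matrix(NA_real_, B, length(labels),
                   dimnames = list(NULL, paste0("M", labels)))
  null_b <- matrix(NA_real_, B, nrow(pairs))
  lines_tab <- expr$samples$line
  cols_a_ln <- cols_a[order(lines_tab[cols_a])]  # line-matched orderings,
  cols_b_ln <- cols_b[order(lines_tab[cols_b])]  # used by paired permutation
  for (bb in seq_len(B)) {
    if (paired) {
      swap <- runif(n_a) < 0.5   # per line, swap the two condition labels
      ca <- ifelse(swap, cols_b_ln, cols_a_ln)
      cb <- ifelse(swap, cols_a_ln, cols_b_ln)
    } else {
      perm <- sample(all_cols)
      ca <- perm[seq_len(n_a)]
      cb <- perm[-seq_len(n_a)]
    }
    st <- stat_all(ca, cb)
    null_w[bb, ] <- st$within
    if (nrow(pairs) > 0) null_b[bb, ] <- st$between
  }

  p_w <- vapply(seq_along(labels), function(i)
    (1 + sum(null_w[, i] >= obs$within[i])) / (B + 1), numeric(1))
  within <- data.frame(module = labels,
                       size = lengths(gene_sets),
                       statistic = unname(obs$within),
                       p = p_w,
                       padj = p.adjust(p_w, "BH"),
                       row.names = NULL)
  within$dc <- within$padj <= alpha

  if (nrow(pairs) > 0) {
    p_b <- vapply(seq_len(nrow(pairs)), function(i)
      (1 + sum(null_b[, i] >= obs$between[i])) / (B + 1), numeric(1))
    btw <- data.frame(module_1 = pairs[, 1], module_2 = pairs[, 2],
                      statistic = unname(obs$between),
                      p = p_b, padj = p.adjust(p_b, "BH"),
                      row.names = NULL)
    btw$dc <- btw$padj <= alpha
  } else {
    btw <- data.frame(module_1 = integer(0), module_2 = integer(0),
                      statistic = numeric(0), p = numeric(0),
                      padj = numeric(0), dc = logical(0))
  }

  structure(list(within = within, between = btw,
                 null_within = null_w, null_between = null_b,
                 B = B, alpha = alpha, beta = beta,
                 paired = paired, seed = seed,
                 conditions = conds),
            class = "dc_report")
}

resolve_pairs <- function(between, labels) {
  if (identical(between, "none") || length(labels) < 2L)
    return(matrix(integer(0), 0, 2))
  if (identical(between, "all"))
    return(t(utils::combn(labels, 2L)))
  m <- as.matrix(between)
  if (ncol(m) != 2L) stop("between must be 'all', 'none' or a 2-column table")
  if (!all(m %in% labels)) stop("between refers to modules absent from the assignment")
  m
}

#' @export
print.dc_report <- function(x, ...) {
  cat("Differential-coexpression permutation test (B = ", x$B,
      ", alpha = ", x$alpha, ")\n", sep = "")
  cat("within-module:\n")
  print(x$within, digits = 4)
  if (nrow(x$between) > 0) {
    cat("between-module pairs flagged DC: ", sum(x$between$dc), "/",
        nrow(x$between), "\n", sep = "")
  }
  invisible(x)
}

#' DC versus non-DC coexpression-strength contrast
#'
#' For each condition, contrasts the coexpression-index distribution of every
#' differentially coexpressed module (within-module pairs; cross pairs for
#' between-module DC) against the pooled within-module pairs of all non-DC
#' modules — the study's null baseline of intrinsic coexpression. Rank-sum
#' tests per DC scope and condition, BH-adjusted within each condition.
#'
#' @param corr_list Named list of the two Spearman correlation matrices, one
#'   per condition (names = condition labels), over the same genes.
#' @param assignment A `module_assignment`.
#' @param report A `dc_report` from [permutation_test()] supplying the DC
#'   flags.
#' @return A `data.frame` with one row per (condition, scope): `condition`,
#'   `scope` (`"non-DC pooled"`, `"module <m>"` or `"modules <i>&<j>"`),
#'   `n_pairs`, `median`, `q25`, `q75`, and for DC rows the rank-sum `W`,
#'   `p`, `padj` against the pooled non-DC baseline.
#' @export
dc_strength_contrast <- function(corr_list, assignment, report) {
  stopifnot(is.list(corr_list), length(corr_list) == 2L,
            !is.null(names(corr_list)))
  dc_within <- report$within$module[report$within$dc]
  non_dc <- report$within$module[!report$within$dc]
  dc_pairs <- report$between[report$between$dc, , drop = FALSE]
  if (length(non_dc) == 0)
    stop("no non-DC modules: the null baseline is undefined")
  if (length(dc_within) == 0 && nrow(dc_pairs) == 0)
    stop("no DC modules or pairs to contrast")

  within_idx <- function(corr, genes) {
    sub <- corr[genes, genes]
    sub[upper.tri(sub)]^2
  }
  cross_idx <- function(corr, ga, gb) as.vector(corr[ga, gb]^2)

  rows <- list()
  for (cond in names(corr_list)) {
    corr <- corr_list[[cond]]
    pooled <- unlist(lapply(non_dc, function(m)
      within_idx(corr, module_genes(assignment, m))))
    rows[[length(rows) + 1L]] <- data.frame(
      condition = cond, scope = "non-DC pooled", n_pairs = length(pooled),
      median = median(pooled), q25 = quantile(pooled, 0.25, names = FALSE),
      q75 = quantile(pooled, 0.75, names = FALSE),
      W = NA_real_, p = NA_real_, padj = NA_real_)
    dc_sets <- c(
      lapply(dc_within, function(m)
        list(scope = paste("module", m),
             idx = within_idx(corr, module_genes(assignment, m)))),
      lapply(seq_len(nrow(dc_pairs)), function(i)
        list(scope = paste0("modules ", dc_pairs$module_1[i], "&",
                            dc_pairs$module_2[i]),
             idx = cross_idx(corr,
                             module_genes(assignment, dc_pairs$module_1[i]),
                             module_genes(assignment, dc_pairs$module_2[i])))))
    ps <- numeric(length(dc_sets))
    for (i in seq_along(dc_sets)) {
      w <- suppressWarnings(wilcox.test(dc_sets[[i]]$idx, pooled))
      ps[i] <- w$p.value
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, scope = dc_sets[[i]]$scope,
        n_pairs = length(dc_sets[[i]]$idx),
        median = median(dc_sets[[i]]$idx),
        q25 = quantile(dc_sets[[i]]$idx, 0.25, names = FALSE),
        q75 = quantile(dc_sets[[i]]$idx, 0.75, names = FALSE),
        W = unname(w$statistic), p = w$p.value, padj = NA_real_)
    }
    padj <- p.adjust(ps, "BH")
    k <- length(rows)
    for (i in seq_along(dc_sets)) rows[[k - length(dc_sets) + i]]$padj <- padj[i]
  }
  do.call(rbind, rows)
}

#' Per-gene expression-variability comparison between conditions
#'
#' Computes each gene's variance and median absolute deviation within each
#' condition and tests, by a paired Wilcoxon signed-rank test across genes,
#' whether variability differs systematically between conditions. Used to
#' check that differential coexpression is not an artifact of one condition
#' simply having noisier expression.
#'
#' @param expr A [coex_expr()] object.
#' @return A list: `per_gene` data.frame (`gene_id`, `var_<cond>`,
#'   `mad_<cond>` for both conditions), `statistic`, `p`, `direction`
#'   (which condition is more variable, or `"no systematic difference"`).
#' @export
expression_variability_check <- function(expr) {
  stopifnot(inherits(expr, "coex_expr"))
  conds <- conditions_of(expr)
  xa <- expr$values[, condition_columns(expr, conds[1]), drop = FALSE]
  xb <- expr$values[, condition_columns(expr, conds[2]), drop = FALSE]
  per_gene <- data.frame(
    gene_id = rownames(expr$values),
    var_a = apply(xa, 1L, var), var_b = apply(xb, 1L, var),
    mad_a = apply(xa, 1L, mad), mad_b = apply(xb, 1L, mad),
    row.names = NULL)
  names(per_gene)[2:5] <- c(paste0("var_", conds), paste0("mad_", conds))
  dv <- per_gene[[2]] - per_gene[[3]]
  if (all(dv == 0)) {
    w <- list(statistic = c(V = 0), p.value = 1)
  } else {
    w <- suppressWarnings(wilcox.test(per_gene[[2]], per_gene[[3]],
                                      paired = TRUE))
  }
  dir <- if (w$p.value > 0.05) "no systematic difference"
         else if (median(dv) > 0) paste(conds[1], "more variable")
         else paste(conds[2], "more variable")
  list(per_gene = per_gene, statistic = unname(w$statistic),
       p = w$p.value, direction = dir)
}
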