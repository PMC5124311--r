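# Independent brute-force oracles and small fixture builders shared across
# test files. Oracles are deliberately naive (explicit loops, no reuse of
# package internals) so they check the implementation from a different path.

# Spearman correlation of two vectors from first principles: average ranks,
# then the Pearson product-moment formula written out longhand.
oracle_spearman_pair <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

oracle_spearman_matrix <- function(values) {
  n <- nrow(values)
  out <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      out[i, j] <- out[j, i] <- oracle_spearman_pair(values[i, ], values[j, ])
    }
  }
  dimnames(out) <- list(rownames(values), rownames(values))
  out
}

# Topological overlap by explicit triple loop.
oracle_tom <- function(d) {
  n <- nrow(d)
  out <- diag(1, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) if (u != i && u != j) l <- l + d[i, u] * d[u, j]
      ki <- sum(d[i, -i])
      kj <- sum(d[j, -j])
      out[i, j] <- (l + d[i, j]) / (min(ki, kj) + 1 - d[i, j])
    }
  }
  dimnames(out) <- dimnames(d)
  out
}

# Upper hypergeometric tail by direct enumeration of the density.
oracle_hyper_upper <- function(k, set_size, bg_size, module_size) {
  kk <- k:min(set_size, module_size)
  sum(choose(set_size, kk) * choose(bg_size - set_size, module_size - kk)) /
    choose(bg_size, module_size)
}

# Expression container with iid Gaussian noise, two conditions.
make_noise_expr <- function(n_genes, n_per_cond, seed = 1) {
  set.seed(seed)
  n_s <- 2 * n_per_cond
  v <- matrix(rnorm(n_genes * n_s), n_genes, n_s,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_s))))
  meta <- data.frame(sample_id = colnames(v),
                     condition = rep(c("A", "B"), each = n_per_cond),
                     line = rep(seq_len(n_per_cond), 2))
  coex_expr(v, meta)
}

# Wrap a planted truth as a module_assignment (fixed gene sets, no detection).
planted_assignment <- function(truth, gene_ids = names(truth$module_of_gene)) {
  m <- truth$module_of_gene[gene_ids]
  sizes <- table(m[m > 0])
  structure(list(modules = m,
                 sizes = stats::setNames(as.integer(sizes), names(sizes)),
                 params = list(source = "planted")),
            class = "module_assignment")
}

# Default-config run up to the expression matrix, shared by several tests.
default_run_to_expr <- function(seed = 1) {
  sim <- simulate_expression(default_study_config(seed = seed))
  expr <- vst_transform(filter_genes(sim$data, min_count = 5))
  list(sim = sim, expr = expr)
}
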