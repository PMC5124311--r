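# Constructed-dissimilarity helpers: a block-diagonal "change" structure
# where within-block dissimilarity is high (a strong shared coexpression
# change) and between-block dissimilarity is low.
block_tom <- function(sizes, within_sim = 0.8, between_sim = 0.05,
                      jitter = 0, seed = 1) {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  tom <- matrix(between_sim, n, n)
  for (b in seq_along(sizes)) tom[lab == b, lab == b] <- within_sim
  if (jitter > 0) {
    set.seed(seed)
    r <- matrix(runif(n * n, -jitter, jitter), n, n)
    tom <- tom + (r + t(r)) / 2
  }
  diag(tom) <- 1
  dimnames(tom) <- list(sprintf("g%03d", 1:n), sprintf("g%03d", 1:n))
  tom
}

test_that("average-linkage merge heights match hand evaluation", {
  # pairwise dissimilarities: d12=0.1 d13=0.4 d23=0.5 d14=0.7 d24=0.8 d34=0.9
  # merges: (1,2)@0.1; ({12},3)@(0.4+0.5)/2=0.45; ({123},4)@(0.7+0.8+0.9)/3
  d <- matrix(0, 4, 4, dimnames = list(paste0("g", 1:4), paste0("g", 1:4)))
  d[1, 2] <- 0.1; d[1, 3] <- 0.4; d[2, 3] <- 0.5
  d[1, 4] <- 0.7; d[2, 4] <- 0.8; d[3, 4] <- 0.9
  d <- d + t(d)
  dendro <- cluster_genes(1 - d)
  expect_equal(dendro$height, c(0.1, 0.45, 0.8))
  expect_identical(dendro$method, "average")
})

test_that("clustering is equivariant under gene permutation", {
  tom <- block_tom(c(10, 10), jitter = 0.02, seed = 2)
  set.seed(5)
  perm <- sample(nrow(tom))
  hc1 <- cluster_genes(tom)
  hc2 <- cluster_genes(tom[perm, perm])
  m1 <- cutree(hc1, k = 2)
  m2 <- cutree(hc2, k = 2)[rownames(tom)]
  expect_equal(mclust::adjustedRandIndex(m1, m2), 1)
})

test_that("first merges happen inside planted blocks", {
  tom <- block_tom(c(8, 8), jitter = 0.02, seed = 3)
  hc <- cluster_genes(tom)
  lab <- rep(1:2, each = 8)
  first <- hc$merge[1:6, ]
  leaves <- -first[first < 0]
  # every leaf joined in the first merges pairs within one block
  for (r in seq_len(6)) {
    mr <- hc$merge[r, ]
    if (all(mr < 0)) expect_equal(lab[-mr[1]], lab[-mr[2]])
  }
})

test_that("the static cut dissolves undersized branches and orders labels by size", {
  tom <- block_tom(c(120, 120, 50), jitter = 0.01, seed = 4)
  asg <- cut_tree(cluster_genes(tom), height_fraction = 0.712, min_size = 100)
  expect_identical(length(asg$sizes), 2L)
  expect_true(all(asg$sizes >= 100))
  lab <- rep(1:3, c(120, 120, 50))
  expect_true(all(asg$modules[lab == 3] == 0))      # 50-gene block unassigned
  expect_true(all(asg$modules[lab == 1] > 0))
  # labels 1..k by decreasing size
  expect_true(all(diff(unname(asg$sizes)) <= 0))
  expect_error(cut_tree(cluster_genes(tom), height_fraction = 1.2), "\\(0, 1\\)")
})

test_that("a two-block structure is fully assigned when min_size allows", {
  tom <- block_tom(c(15, 25), jitter = 0.01, seed = 6)
  asg <- cut_tree(cluster_genes(tom), min_size = 10)
  expect_identical(unname(asg$sizes), c(25L, 15L))
  expect_true(all(asg$modules > 0))
})

test_that("eigengenes match the rank-1 and antisymmetric closed forms", {
  # module of identical genes: eigengene is the standardized common profile
  profile <- c(1, 3, 2, 5, 4, 6)
  v <- rbind(g1 = profile, g2 = profile, g3 = profile)
  colnames(v) <- paste0("s", 1:6)
  meta <- data.frame(sample_id = colnames(v),
                     condition = rep(c("A", "B"), each = 3), line = rep(1:3, 2))
  expr <- coex_expr(v, meta)
  asg <- structure(list(modules = setNames(c(1L, 1L, 1L), rownames(v)),
                        sizes = c(`1` = 3L), params = list()),
                   class = "module_assignment")
  eig <- module_eigengene(expr, asg)
  z <- scale(profile)[, 1]
  expect_equal(unname(eig[1, ]), z / sqrt(sum(z^2)))
  expect_equal(unname(attr(eig, "var_explained")), 1)

  # two genes that are exact negatives after standardization: mean profile
  # cancels, sign aligns with the first gene
  v2 <- rbind(g1 = profile, g2 = max(profile) - profile)
  colnames(v2) <- paste0("s", 1:6)
  expr2 <- coex_expr(v2, meta)
  asg2 <- structure(list(modules = setNames(c(1L, 1L), rownames(v2)),
                         sizes = c(`1` = 2L), params = list()),
                    class = "module_assignment")
  eig2 <- module_eigengene(expr2, asg2)
  expect_equal(unname(attr(eig2, "var_explained")), 1)
  expect_gt(cor(eig2[1, ], profile), 0.99)
})

test_that("eigengene equals the first singular vector from a full decomposition", {
  expr <- make_noise_expr(10, 8, seed = 7)
  asg <- structure(list(modules = setNames(rep(1L, 10), rownames(expr$values)),
                        sizes = c(`1` = 10L), params = list()),
                   class = "module_assignment")
  eig <- module_eigengene(expr, asg)
  xs <- t(scale(t(expr$values)))
  ref <- eigen(crossprod(xs))$vectors[, 1]       # independent decomposition
  ref <- ref / sqrt(sum(ref^2))
  err <- min(max(abs(eig[1, ] - ref)), max(abs(eig[1, ] + ref)))
  expect_lt(err, 1e-10)
  expect_gte(cor(eig[1, ], colMeans(xs)), 0)     # sign rule
})

test_that("zero-variance member genes are an error naming the module", {
  expr <- make_noise_expr(5, 4, seed = 8)
  expr$values[2, ] <- 3
  asg <- structure(list(modules = setNames(rep(1L, 5), rownames(expr$values)),
                        sizes = c(`1` = 5L), params = list()),
                   class = "module_assignment")
  expect_error(module_eigengene(expr, asg), "module 1 contains zero-variance")
})

test_that("modules driven by one factor merge; orthogonal modules do not", {
  set.seed(23)
  n_s <- 20
  f1 <- rnorm(n_s); f2 <- rnorm(n_s)
  v <- rbind(matrix(rep(f1, each = 10), 10, n_s) + rnorm(10 * n_s, 0, 0.3),
             matrix(rep(f1, each = 10), 10, n_s) + rnorm(10 * n_s, 0, 0.3),
             matrix(rep(f2, each = 10), 10, n_s) + rnorm(10 * n_s, 0, 0.3))
  dimnames(v) <- list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:n_s))
  meta <- data.frame(sample_id = colnames(v),
                     condition = rep(c("A", "B"), each = n_s / 2),
                     line = rep(seq_len(n_s / 2), 2))
  expr <- coex_expr(v, meta)
  # modules 1 and 2 both follow f1 (an artificially split block); 3 follows f2
  asg <- structure(list(modules = setNames(rep(1:3, each = 10), rownames(v)),
                        sizes = setNames(rep(10L, 3), 1:3), params = list()),
                   class = "module_assignment")
  merged <- merge_similar_modules(expr, asg, merge_height = 0.2)
  expect_identical(length(merged$sizes), 2L)
  expect_identical(unname(merged$sizes), c(20L, 10L))
  m_split <- unique(merged$modules[1:20])
  expect_length(m_split, 1)

  # identical eigengenes always merge, even at merge_height = 0
  same <- structure(list(modules = setNames(rep(1:2, each = 15), rownames(v)[1:30]),
                         sizes = setNames(c(15L, 15L), 1:2), params = list()),
                    class = "module_assignment")
  # distinct eigengenes, zero height: nothing merges
  kept <- merge_similar_modules(expr, asg, merge_height = 0)
  expect_identical(length(kept$sizes), 3L)
})

test_that("merging is idempotent", {
  run <- default_run_to_expr(seed = 4)
  rho <- lapply(conditions_of(run$expr),
                function(cc) spearman_matrix(run$expr, cc))
  d <- difference_dissimilarity(signed_adjacency(rho[[1]]),
                                signed_adjacency(rho[[2]]), beta = 4)
  asg <- cut_tree(cluster_genes(topological_overlap(d)), min_size = 30)
  m1 <- merge_similar_modules(run$expr, asg)
  m2 <- merge_similar_modules(run$expr, m1)
  expect_identical(m1$modules, m2$modules)
})

test_that("module means equal an explicit loop and carry condition summaries", {
  expr <- make_noise_expr(12, 5, seed = 31)
  asg <- structure(list(modules = setNames(c(rep(1L, 7), rep(2L, 5)),
                                           rownames(expr$values)),
                        sizes = c(`1` = 7L, `2` = 5L), params = list()),
                   class = "module_assignment")
  mm <- module_mean_expression(expr, asg)
  ref <- matrix(0, 2, ncol(expr$values))
  for (s in seq_len(ncol(expr$values))) {
    ref[1, s] <- mean(expr$values[1:7, s])
    ref[2, s] <- mean(expr$values[8:12, s])
  }
  expect_equal(unname(mm), ref, ignore_attr = TRUE)
  cm <- attr(mm, "condition_means")
  expect_equal(cm["M1", "A"],
               mean(mm["M1", condition_columns(expr, "A")]))

  single <- structure(list(modules = setNames(c(1L, rep(0L, 11)),
                                              rownames(expr$values)),
                           sizes = c(`1` = 1L), params = list()),
                      class = "module_assignment")
  expect_equal(unname(module_mean_expression(expr, single)[1, ]),
               unname(expr$values[1, ]))
})
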