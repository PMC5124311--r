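test_that("dispersion statistic matches hand-evaluated pair sets", {
  nm <- paste0("g", 1:5)
  d <- matrix(0, 5, 5, dimnames = list(nm, nm))
  expect_equal(dispersion_statistic(d, nm[1:3]), 0)

  d[1, 2] <- d[2, 1] <- 1; d[1, 3] <- d[3, 1] <- 1; d[2, 3] <- d[3, 2] <- 1
  expect_equal(dispersion_statistic(d, nm[1:3]), 1)

  d[1, 2] <- d[2, 1] <- 0.6; d[1, 3] <- d[3, 1] <- 0; d[2, 3] <- d[3, 2] <- 0.8
  expect_equal(dispersion_statistic(d, nm[1:3]),
               sqrt((0.36 + 0 + 0.64) / 3))

  d[4, 5] <- d[5, 4] <- 1
  d[1, 4] <- d[4, 1] <- 0.5; d[1, 5] <- d[5, 1] <- 0.5
  # between mode averages over cross pairs only: (0.25+0.25+0+0+0+0)/6
  expect_equal(dispersion_statistic(d, nm[1:3], nm[4:5]),
               sqrt((0.25 + 0.25) / 6))
  expect_error(dispersion_statistic(d, nm[1:3], nm[3:5]), "overlap")
  expect_error(dispersion_statistic(d, nm[1]), ">= 2 genes")
})

test_that("permutation p-values obey the add-one formula and its bounds", {
  # an extreme planted change: observed should beat every null draw,
  # forcing p to its lower bound 1/(B+1)
  cfg <- sim_config(n_genes = 40, n_samples_per_condition = 10,
                    module_specs = list(module_spec(30, 0.9, 0)),
                    output = "gaussian", seed = 41)
  sim <- simulate_expression(cfg)
  asg <- planted_assignment(sim$truth)
  rep <- permutation_test(sim$data, asg, B = 19, between = "none", seed = 5)
  expect_equal(rep$within$p, 1 / 20)
  expect_identical(dim(rep$null_within), c(19L, 1L))

  # bounds hold for every test in a multi-module run
  run <- permutation_test(sim$data,
                          planted_assignment(sim$truth), B = 9, seed = 6)
  expect_true(all(run$within$p >= 1 / 10 & run$within$p <= 1))
  expect_error(permutation_test(sim$data, asg, B = 0), "B must be")
})

test_that("permutations are reproducible under a fixed seed", {
  cfg <- sim_config(n_genes = 30, n_samples_per_condition = 6,
                    module_specs = list(module_spec(10, 0.6, 0.1),
                                        module_spec(10, 0.4, 0.4)),
                    output = "gaussian", seed = 43)
  sim <- simulate_expression(cfg)
  asg <- planted_assignment(sim$truth)
  r1 <- permutation_test(sim$data, asg, B = 29, seed = 11)
  r2 <- permutation_test(sim$data, asg, B = 29, seed = 11)
  expect_identical(r1$within, r2$within)
  expect_identical(r1$null_between, r2$null_between)
  r3 <- permutation_test(sim$data, asg, B = 29, seed = 12)
  expect_false(identical(r1$null_within, r3$null_within))
})

test_that("a planted differential module is detected and an invariant one is not", {
  cfg <- sim_config(n_genes = 120, n_samples_per_condition = 17,
                    module_specs = list(module_spec(50, 0.7, 0.1),
                                        module_spec(40, 0.5, 0.5)),
                    output = "gaussian", seed = 47)
  sim <- simulate_expression(cfg)
  rep <- permutation_test(sim$data, planted_assignment(sim$truth),
                          B = 199, between = "none", seed = 13)
  expect_true(rep$within$dc[1])
  expect_false(rep$within$dc[2])
})

test_that("rejection power rises with the planted loading gap", {
  gaps <- c(0, 0.3, 0.6)
  pmat <- sapply(gaps, function(g) {
    sapply(1:8, function(s) {
      cfg <- sim_config(n_genes = 60, n_samples_per_condition = 17,
                        module_specs = list(module_spec(60, 0.1 + g, 0.1)),
                        output = "gaussian", seed = 600 + 31 * s)
      sim <- simulate_expression(cfg)
      permutation_test(sim$data, planted_assignment(sim$truth),
                       B = 99, between = "none", seed = s)$within$p
    })
  })
  med <- apply(pmat, 2, median)
  expect_true(all(diff(med) <= 0))          # p falls as the gap grows
  expect_gte(mean(pmat[, 3] <= 0.05), 0.9)  # clear power at gap 0.6
})

test_that("between-module rewiring is flagged for the planted pair only", {
  cfg <- sim_config(n_genes = 120, n_samples_per_condition = 17,
                    module_specs = list(
                      module_spec(40, 0.5, 0.5),
                      module_spec(40, 0.5, 0.5, cross_partner = 1L,
                                  cross_loading_a = 0.6, cross_loading_b = 0),
                      module_spec(30, 0.5, 0.5)),
                    output = "gaussian", seed = 8001)
  sim <- simulate_expression(cfg)
  rep <- permutation_test(sim$data, planted_assignment(sim$truth),
                          B = 199, seed = 17)
  flagged <- rep$between[rep$between$dc, c("module_1", "module_2")]
  expect_true(any(flagged$module_1 == 1 & flagged$module_2 == 2))
  # the pairs without planted rewiring stay quiet
  expect_false(any(flagged$module_2 == 3))
  # the planted pair carries the largest observed cross-dispersion
  expect_identical(which.max(rep$between$statistic), 1L)
})

test_that("strength contrast orders DC modules above the non-DC pool in the strong condition", {
  cfg <- sim_config(n_genes = 150, n_samples_per_condition = 17,
                    module_specs = list(module_spec(50, 0.75, 0.1),
                                        module_spec(40, 0.4, 0.4),
                                        module_spec(40, 0.35, 0.35)),
                    output = "gaussian", seed = 59)
  sim <- simulate_expression(cfg)
  asg <- planted_assignment(sim$truth)
  rep <- permutation_test(sim$data, asg, B = 199, between = "none", seed = 19)
  expect_identical(rep$within$dc, c(TRUE, FALSE, FALSE))
  corr <- lapply(conditions_of(sim$data),
                 function(cc) spearman_matrix(sim$data, cc))
  names(corr) <- conditions_of(sim$data)
  st <- dc_strength_contrast(corr, asg, rep)
  pool_a <- st$median[st$condition == "A" & st$scope == "non-DC pooled"]
  dc_a <- st$median[st$condition == "A" & st$scope == "module 1"]
  pool_b <- st$median[st$condition == "B" & st$scope == "non-DC pooled"]
  dc_b <- st$median[st$condition == "B" & st$scope == "module 1"]
  expect_gt(dc_a, pool_a)
  expect_lt(st$padj[st$condition == "A" & st$scope == "module 1"], 0.01)
  expect_lt(dc_b, pool_b)

  all_dc <- rep
  all_dc$within$dc <- c(TRUE, TRUE, TRUE)
  expect_error(dc_strength_contrast(corr, asg, all_dc), "baseline")
})

test_that("variability check reports forced and null differences correctly", {
  expr <- make_noise_expr(40, 6, seed = 61)
  # identical per-condition submatrices
  v <- expr$values
  v[, 7:12] <- v[, 1:6]
  same <- coex_expr(v, expr$samples)
  chk <- expression_variability_check(same)
  expect_equal(chk$p, 1)
  expect_match(chk$direction, "no systematic difference")

  # condition B scaled x2 about gene means: var greater in B for every gene
  v2 <- expr$values
  mu <- rowMeans(v2[, 1:6])
  v2[, 7:12] <- (v2[, 1:6] - mu) * 2 + mu
  scaled <- coex_expr(v2, expr$samples)
  chk2 <- expression_variability_check(scaled)
  expect_true(all(chk2$per_gene$var_B > chk2$per_gene$var_A))
  expect_match(chk2$direction, "B more variable")
  expect_lt(chk2$p, 1e-6)

  # equal noise in both conditions: no systematic difference
  chk3 <- expression_variability_check(make_noise_expr(300, 10, seed = 67))
  expect_match(chk3$direction, "no systematic difference")
})
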