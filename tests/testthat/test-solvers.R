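test_that("exhaustive MQSS recovers the generator from a perfect matrix", {
  sig <- balanced6()
  sim <- simulate_mutation_matrix(sig, error_model(0, 0, 0), k = 300,
                                  seed = 73)
  res <- mqss_exhaustive(sim$D)
  expect_equal(res$evaluations, 105L)
  err <- tree_error(sig, res$tree)
  expect_equal(err$fn, 0)
  expect_equal(err$fp, 0)
  # reported score is consistent with independent recomputation
  expect_equal(res$score, quartet_support(sim$D, res$tree))
})

test_that("MQSS on a polytomous generator returns a refinement", {
  sig <- poly6()
  sim <- simulate_mutation_matrix(sig, error_model(0, 0, 0), k = 400,
                                  seed = 79)
  res <- mqss_exhaustive(sim$D)
  expect_true(is_refinement(res$tree, unroot_lineage(sig)))
  expect_equal(tree_error(sig, res$tree)$fn, 0)
})

test_that("constrained search matches exhaustive given a perfect matrix", {
  sig <- balanced6()
  sim <- simulate_mutation_matrix(sig, error_model(0, 0, 0), k = 300,
                                  seed = 83)
  sp <- build_constraint_space(sim$D)
  res_c <- mqss_constrained(sim$D, sp)
  res_e <- mqss_exhaustive(sim$D)
  expect_equal(res_c$score, res_e$score)
  expect_equal(tree_error(sig, res_c$tree)$fn, 0)
  # a singleton constraint space returns its own tree
  tstar <- random_binary_topology(rownames(sim$D), seed = 4)
  sp1 <- build_constraint_space(sim$D[, 0, drop = FALSE], extra = list(tstar))
  res1 <- mqss_constrained(sim$D, sp1)
  expect_equal(canonical_newick(res1$tree), canonical_newick(tstar))
  expect_equal(res1$evaluations, 1L)
})

test_that("constrained optimum never exceeds the exhaustive optimum", {
  set.seed(89)
  for (i in 1:4) {
    sig <- random_lineage_tree(6, resolution = 1)
    sim <- simulate_mutation_matrix(sig, error_model(0.1, 0.2, 0.2),
                                    k = 150, seed = 100 + i)
    sp <- build_constraint_space(sim$D,
                                 extra = list(random_binary_topology(
                                   rownames(sim$D))))
    res_e <- mqss_exhaustive(sim$D)
    res_c <- tryCatch(mqss_constrained(sim$D, sp),
                      error = function(e) NULL)
    if (!is.null(res_c)) expect_lte(res_c$score, res_e$score)
  }
})

test_that("constraint space completion handles missing cells as configured", {
  D <- matrix(c(1L, 1L, NA, 0L, 0L, 0L), ncol = 1,
              dimnames = list(paste0("c", 1:6), "m1"))
  sp_zero <- build_constraint_space(D, completion = "zero")
  expect_equal(length(sp_zero$masks), 1L)
  sp_drop <- build_constraint_space(D, completion = "drop")
  expect_equal(length(sp_drop$masks), 0L)
})

test_that("NNI search is monotone and finds small optima", {
  sig <- balanced6()
  sim <- simulate_mutation_matrix(sig, error_model(0.05, 0.2, 0.1),
                                  k = 500, seed = 101)
  opt <- mqss_exhaustive(sim$D)
  # starting from the optimum stays at the optimum
  stay <- mqss_nni(sim$D, start = opt$tree, seed = 1)
  expect_equal(stay$score, opt$score)
  # random starts never decrease and usually reach the optimum
  hits <- 0
  for (s in 1:5) {
    start <- random_binary_topology(rownames(sim$D), seed = 200 + s)
    start_score <- quartet_support(sim$D, start)
    res <- mqss_nni(sim$D, start = start, seed = 300 + s)
    expect_gte(res$score, start_score)
    expect_equal(res$score, quartet_support(sim$D, res$tree))
    if (res$score == opt$score) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("exhaustive MTSS recovers a rooted generator from perfect data", {
  sig <- balanced6()
  sim <- simulate_mutation_matrix(sig, error_model(0, 0, 0), k = 300,
                                  seed = 103)
  res <- mtss_exhaustive(sim$D)
  expect_equal(res$evaluations, 945L)
  expect_equal(tree_error(sig, res$tree)$fn, 0)
  expect_equal(res$score, triplet_support(sim$D, res$tree))
})

test_that("the consistency harness is deterministic and exact at zero error", {
  sig <- balanced6()
  tab1 <- consistency_experiment(sig, error_model(0, 0, 0),
                                 k_grid = c(30, 100), replicates = 3,
                                 solver = "mqss", seed = 7)
  tab2 <- consistency_experiment(sig, error_model(0, 0, 0),
                                 k_grid = c(30, 100), replicates = 3,
                                 solver = "mqss", seed = 7)
  expect_identical(tab1, tab2)
  expect_equal(nrow(tab1), 6)
  expect_true(all(tab1$fn == 0))
  # FN error does not increase from the smallest to the largest k
  em <- error_model(0.1, 0.25, 0.1)
  tab3 <- consistency_experiment(sig, em, k_grid = c(40, 2000),
                                 replicates = 8, solver = "mqss", seed = 11)
  m <- tapply(tab3$fn, tab3$k, mean)
  expect_lte(m[["2000"]], m[["40"]])
})

test_that("QS of a refinement beats QS of a non-refinement as k grows", {
  sig <- poly6()
  u <- unroot_lineage(sig)
  B <- NULL; T_bad <- NULL
  for (tr in enumerate_unrooted_binary(sig$tip.label)) {
    if (is.null(B) && is_refinement(tr, u)) B <- tr
    if (is.null(T_bad) && !is_refinement(tr, u)) T_bad <- tr
    if (!is.null(B) && !is.null(T_bad)) break
  }
  em <- error_model(0.05, 0.2, 0.1)
  wins <- integer(3)
  ks <- c(100, 1000, 10000)
  for (gi in seq_along(ks)) {
    for (r in 1:5) {
      sim <- simulate_mutation_matrix(sig, em, k = ks[gi],
                                      seed = 5000 + 100 * gi + r)
      tab <- quartet_weights(sim$D)
      if (quartet_support(tab, B) > quartet_support(tab, T_bad)) {
        wins[gi] <- wins[gi] + 1L
      }
    }
  }
  expect_equal(wins[3], 5L)
  expect_gte(wins[3], wins[1])
})
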