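test_that("error model validates its domain and flags the degenerate line", {
  expect_error(error_model(1, 0, 0), "\\[0, 1\\)")
  expect_error(error_model(-0.1, 0, 0))
  expect_warning(em <- error_model(0.5, 0.5, 0), "alpha \\+ beta")
  expect_true(em$degenerate)
  emx <- error_model(ratio(1, 1000), ratio(1, 5))
  expect_true(emx$exact)
})

test_that("IS pattern distribution puts one pattern per edge", {
  t <- read_lineage_tree("((A:0.25,B:0.25):0.25,C:0.25);")
  pd <- is_pattern_distribution(t, c("A", "B", "C"))
  expect_equal(pd$prob[["100"]], 0.25)
  expect_equal(pd$prob[["010"]], 0.25)
  expect_equal(pd$prob[["001"]], 0.25)
  expect_equal(pd$prob[["110"]], 0.25)
  expect_equal(sum(pd$prob), 1)
  expect_equal(sum(pd$prob > 0), 4)
})

test_that("pattern distribution is invariant to computing on the restriction", {
  set.seed(13)
  for (i in 1:8) {
    sig <- random_lineage_tree(8, resolution = stats::runif(1, 0.3, 1))
    sub <- sample(sig$tip.label, 4)
    direct <- is_pattern_distribution(sig, sub)
    via_restrict <- is_pattern_distribution(restrict_tree(sig, sub), sub)
    expect_equal(direct$prob, via_restrict$prob, tolerance = 1e-12)
  }
})

test_that("pattern distributions marginalise consistently", {
  set.seed(17)
  for (i in 1:5) {
    sig <- random_lineage_tree(7, resolution = stats::runif(1, 0.3, 1))
    big <- sample(sig$tip.label, 5)
    small <- big[1:3]
    pd5 <- is_pattern_distribution(sig, big)
    pd3 <- is_pattern_distribution(sig, small)
    # marginalise pd5 over the last two positions
    marg <- numeric(8)
    for (m in 0:31) {
      marg[bitwAnd(m, 7L) + 1L] <- marg[bitwAnd(m, 7L) + 1L] + pd5$prob[m + 1]
    }
    expect_equal(unname(pd3$prob), marg, tolerance = 1e-12)
  }
})

test_that("the per-entry channel multiplies case probabilities", {
  em <- error_model(0.1, 0, 0)
  expect_equal(uem_channel("0", "1", em), 0.1)
  em2 <- error_model(0, 0.2, 0)
  expect_equal(uem_channel("11", "11", em2), 0.64)
  em3 <- error_model(0.3, 0.1, 0.5)
  expect_equal(uem_channel("01", "??", em3), 0.25)
  expect_equal(uem_channel("01", "01", em3), (1 - 0.3) * (1 - 0.1) * 0.25)
  expect_error(uem_channel("0", "10", em), "unequal")
  expect_error(uem_channel("2", "1", em), "\\{0,1\\}")
})

test_that("the corruption oracle conserves mass and reduces to identity", {
  t <- build_shape_tree("S2")
  base <- is_pattern_distribution(t, c("A", "B", "C", "D"))
  id <- corrupted_pattern_distribution(base, error_model(0, 0, 0))
  expect_equal(id$prob[match(base$patterns, id$patterns)],
               unname(base$prob), ignore_attr = TRUE, tolerance = 1e-15)
  set.seed(29)
  for (i in 1:10) {
    em <- random_error_model()
    cor <- corrupted_pattern_distribution(base, em)
    expect_equal(sum(cor$prob), 1, tolerance = 1e-12)
    expect_true(all(cor$prob >= 0))
  }
  # exact mode conserves mass exactly (error-only channel; the worked
  # parameter corner keeps denominators inside exact double range)
  emx <- error_model(ratio(1, 1000), ratio(1, 5))
  corx <- corrupted_pattern_distribution(base, emx)
  expect_true(sum(corx$exact) == ratio(1))
})

test_that("a single false negative on a cherry pattern has the table weight", {
  # base concentrated on 1100: observing 0100 costs one false negative and
  # three faithful copies: beta (1-beta) (1-alpha)^2
  base <- list(labels = c("A", "B", "C", "D"),
               patterns = quartetlineage:::.pattern_strings(4),
               prob = c(numeric(3), 1, numeric(12)), exact = NULL)
  names(base$prob) <- base$patterns
  class(base) <- "pattern_distribution"
  em <- error_model(0.1, 0.2, 0)
  cor <- corrupted_pattern_distribution(base, em)
  expect_equal(cor$prob[["0100"]], 0.2 * (1 - 0.2) * (1 - 0.1)^2,
               tolerance = 1e-14)
  expect_equal(cor$prob[["1100"]], (1 - 0.2)^2 * (1 - 0.1)^2,
               tolerance = 1e-14)
  expect_equal(cor$prob[["1111"]], (1 - 0.2)^2 * 0.1^2, tolerance = 1e-14)
})

test_that("closed-form quartet probabilities equal the enumeration oracle", {
  set.seed(41)
  shapes <- lapply(paste0("S", 1:5), build_shape_tree)
  for (i in 1:50) {
    em <- random_error_model()
    sh <- shapes[[sample.int(5, 1)]]
    qd <- quartet_distribution_uem(sh, c("A", "B", "C", "D"), em)
    expect_equal(unname(qd$q), oracle_quartet_probs(sh, LETTERS[1:4], em),
                 tolerance = 1e-12)
  }
})

test_that("closed-form triplet probabilities equal the enumeration oracle", {
  set.seed(43)
  shapes <- list(triplet_shape_binary(), triplet_shape_star())
  for (i in 1:50) {
    em <- random_error_model()
    sh <- shapes[[sample.int(2, 1)]]
    td <- triplet_distribution_uem(sh, c("A", "B", "C"), em)
    expect_equal(unname(td$t), oracle_triplet_probs(sh, LETTERS[1:3], em),
                 tolerance = 1e-12)
  }
})

test_that("pairwise quartet differences shrink by the retention factor", {
  set.seed(47)
  for (i in 1:20) {
    sig <- random_lineage_tree(7, resolution = stats::runif(1, 0.3, 1))
    sub <- sample(sig$tip.label, 4)
    em <- random_error_model()
    qd <- quartet_distribution_uem(sig, sub, em)
    fac <- (1 - (em$a + em$b))^2 * (1 - em$g)^4
    for (i1 in 1:2) for (i2 in (i1 + 1):3) {
      expect_equal(qd$q[i1] - qd$q[i2],
                   fac * (qd$q_is[i1] - qd$q_is[i2]),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})

test_that("the retention gap identity holds and vanishes on the line", {
  g <- quartet_error_gap(error_model(0.3, 0.4))
  expect_equal(g$expanded, 0.09, tolerance = 1e-14)
  expect_equal(g$factored, 0.09, tolerance = 1e-14)
  suppressWarnings(gd <- quartet_error_gap(error_model(0.5, 0.5)))
  expect_equal(gd$factored, 0, tolerance = 1e-14)
  expect_equal(gd$expanded, 0, tolerance = 1e-14)
  g0 <- quartet_error_gap(error_model(0, 0))
  expect_equal(g0$expanded, 1)
  set.seed(53)
  for (i in 1:20) {
    em <- random_error_model()
    g <- quartet_error_gap(em)
    expect_equal(g$expanded, g$factored, tolerance = 1e-14)
  }
})

test_that("under IS alone at most one topology per subset has mass", {
  set.seed(59)
  for (i in 1:10) {
    sig <- random_lineage_tree(7, resolution = stats::runif(1, 0.2, 1))
    sub4 <- sample(sig$tip.label, 4)
    qd <- quartet_distribution_uem(sig, sub4, error_model(0, 0, 0))
    expect_lte(sum(qd$q > 1e-15), 1)
    sub3 <- sample(sig$tip.label, 3)
    td <- triplet_distribution_uem(sig, sub3, error_model(0, 0, 0))
    expect_lte(sum(td$t > 1e-15), 1)
  }
})

test_that("triplet anomaly condition reproduces the worked threshold", {
  emx <- error_model(ratio(1, 1000), ratio(1, 5))
  expect_true(emx$alpha / (1 - emx$beta) == ratio(1, 800))
  # fixture values: px_10 = 1009/1012, px_4 = 1/1012, pt_10 = 1/1012, pt_4 = 0
  expect_true(triplet_anomaly_condition(ratio(1009, 1012), ratio(1, 1012),
                                        ratio(1, 1012), ratio(0), emx))
  # alpha = 0 can never produce an anomaly when pt_i > pt_j
  em0 <- error_model(ratio(0), ratio(1, 5))
  expect_false(triplet_anomaly_condition(ratio(1009, 1012), ratio(1, 1012),
                                         ratio(1, 1012), ratio(0), em0))
})

test_that("quartet scans find no anomalies; the fixture triplet scan does", {
  fx <- build_augmented_lineage_fixture(1000)
  emx <- error_model(ratio(1, 1000), ratio(1, 5))
  rep3 <- find_anomalies(fx, emx, mode = "triplet",
                         subsets = list(c("1", "4", "10")))
  expect_equal(rep3$displayed, "10|1,4")
  expect_setequal(strsplit(rep3$anomalous, "; ")[[1]],
                  c("1|10,4", "4|1,10"))
  # same subset under alpha = 0: no anomaly
  rep0 <- find_anomalies(fx, error_model(ratio(0), ratio(1, 5)),
                         mode = "triplet",
                         subsets = list(c("1", "4", "10")))
  expect_equal(rep0$anomalous, "")
  # quartet mode on random instances: never anomalous
  set.seed(61)
  for (i in 1:10) {
    sig <- random_lineage_tree(6, resolution = stats::runif(1, 0.3, 1))
    em <- random_error_model()
    rep <- find_anomalies(sig, em, mode = "quartet")
    expect_true(all(rep$anomalous == ""))
  }
  # triplet mode with alpha = 0 on random instances: never anomalous
  for (i in 1:5) {
    sig <- random_lineage_tree(6, resolution = stats::runif(1, 0.3, 1))
    em <- error_model(0, stats::runif(1, 0, 0.4), stats::runif(1, 0, 0.3))
    rep <- find_anomalies(sig, em, mode = "triplet")
    expect_true(all(rep$anomalous == ""))
  }
})
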