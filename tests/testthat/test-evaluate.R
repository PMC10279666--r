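test_that("KNN classifies by Euclidean majority vote", {
  # a single-class training set predicts that class everywhere
  set.seed(31)
  tr <- matrix(rnorm(20), 10, 2)
  pred <- knnClassify(tr, matrix(rnorm(10), 5, 2), k = 3,
                      train_labels = rep(2L, 10))
  expect_identical(pred, rep(2L, 5))
  # two well-separated Gaussian clusters: perfect held-out accuracy
  set.seed(32)
  Xtr <- rbind(matrix(rnorm(60), 30, 2), matrix(rnorm(60, mean = 10), 30, 2))
  ytr <- rep(1:2, each = 30)
  Xte <- rbind(matrix(rnorm(20), 10, 2), matrix(rnorm(20, mean = 10), 10, 2))
  expect_identical(knnClassify(Xtr, Xte, k = 6, train_labels = ytr),
                   rep(1:2, each = 10))
  expect_error(knnClassify(Xtr, Xte, k = 61, train_labels = ytr), "exceed")
  expect_error(knnClassify(Xtr, Xte[, 1, drop = FALSE], k = 6,
                           train_labels = ytr), "width")
})

test_that("KNN tie rules are deterministic", {
  # 3-3 vote tie at k = 6: the single nearest neighbour decides
  tr <- matrix(c(1, 2, 3, -1.5, -2.5, -3.5), ncol = 1)
  y <- c(1L, 1L, 1L, 2L, 2L, 2L)
  expect_identical(knnClassify(tr, matrix(0), k = 6, train_labels = y), 1L)
  tr2 <- matrix(c(1.5, 2.5, 3.5, -1, -2, -3), ncol = 1)
  expect_identical(knnClassify(tr2, matrix(0), k = 6, train_labels = y), 2L)
  # equidistant neighbours: the lower training index wins
  tr3 <- matrix(c(1, -1), ncol = 1)
  expect_identical(knnClassify(tr3, matrix(0), k = 1, train_labels = c(1L, 2L)),
                   1L)
  expect_identical(knnClassify(tr3[2:1, , drop = FALSE], matrix(0), k = 1,
                               train_labels = c(2L, 1L)), 2L)
})

test_that("KNN agrees with an independent implementation on tie-free data", {
  skip_if_not_installed("class")
  set.seed(33)
  Xtr <- matrix(rnorm(120), 40, 3)
  ytr <- rep(1:2, 20)
  Xte <- matrix(rnorm(30), 10, 3)
  ours <- knnClassify(Xtr, Xte, k = 3, train_labels = ytr)
  ref <- as.integer(as.character(class::knn(Xtr, Xte, factor(ytr), k = 3)))
  expect_identical(ours, ref)
})

test_that("confusion matrix counts predictions against truth", {
  cm <- confusionMatrix(c(1, 2, 3), c(1, 2, 3), 3L)
  expect_identical(unname(confusionCounts(cm)), diag(1L, 3L))
  # hand count: pred (1,1,2,2) vs truth (1,2,1,2)
  cm2 <- confusionMatrix(c(1, 1, 2, 2), c(1, 2, 1, 2), 2L)
  expect_identical(unname(confusionCounts(cm2)),
                   matrix(1L, 2, 2))
  # empty input gives the zero matrix
  cm0 <- confusionMatrix(integer(0), integer(0), 2L)
  expect_identical(sum(confusionCounts(cm0)), 0L)
  expect_error(confusionMatrix(c(1, 4), c(1, 2), 3L), "range")
  expect_error(confusionMatrix(c(1, 2), c(1, 2, 1), 3L), "equal length")
})

test_that("metrics follow the confusion-matrix definitions", {
  perfect <- evalMetrics(diag(5L, 4))
  expect_identical(accuracyOf(perfect), 1)
  expect_true(all(perClassMetrics(perfect)[, c("precision", "recall", "f1")] == 1))
  r <- evalMetrics(matrix(c(40, 10, 10, 40), 2))
  expect_equal(accuracyOf(r), 0.8)
  expect_equal(unname(macroMetrics(r)), rep(0.8, 3))
  expect_equal(perClassMetrics(r)$precision, c(0.8, 0.8))
  # constant predictor on balanced 8-class truth: accuracy 1/N
  M <- matrix(0L, 8, 8); M[1, ] <- 10L
  expect_warning(rc <- evalMetrics(M), "zero")
  expect_equal(accuracyOf(rc), 0.125)
  expect_equal(perClassMetrics(rc)$recall[1], 1)
  expect_equal(perClassMetrics(rc)$precision[2], 0)
  expect_error(evalMetrics(matrix(0L, 2, 2)), "empty")
})

test_that("metric invariants hold on random confusion matrices", {
  set.seed(34)
  for (i in 1:20) {
    N <- sample(2:6, 1)
    M <- matrix(rpois(N * N, 5) + 1L, N, N)
    r <- evalMetrics(M)
    expect_equal(accuracyOf(r), sum(diag(M)) / sum(M))
    pc <- perClassMetrics(r)
    expect_gte(macroMetrics(r)["f1"], min(pc$f1))
    expect_lte(macroMetrics(r)["f1"], max(pc$f1))
    # micro precision (diagonal over predicted totals) equals accuracy
    expect_equal(sum(diag(M)) / sum(rowSums(M)), accuracyOf(r))
  }
})

test_that("stratified folds deal every class evenly and disjointly", {
  labels <- rep(1:8, each = 625)
  fold <- stratifiedFolds(labels, folds = 5L, seed = 3L)
  for (f in 1:5) for (cl in 1:8) {
    expect_identical(sum(fold == f & labels == cl), 125L)
    expect_identical(sum(fold != f & labels == cl), 500L)
  }
  # partitions are disjoint and cover everything by construction of a
  # single assignment vector; check the assignment is complete
  expect_true(all(fold %in% 1:5))
  expect_length(fold, 5000L)
  # reproducible
  expect_identical(fold, stratifiedFolds(labels, 5L, seed = 3L))
  expect_error(stratifiedFolds(labels, folds = 1L), "folds")
  expect_error(stratifiedFolds(c(1, 1, 2), folds = 2L), "at least")
})

test_that("cross-validation reports fold metrics and their spread", {
  pf <- planted_sep()
  fm <- FeatureMatrix(pf$values, pf$labels, "train")
  cv <- crossValidate(fm, k = 6L, folds = 5L, seed = 2L)
  expect_length(cv$reports, 5L)
  expect_identical(cv$summary$metric, c("accuracy", "precision", "recall", "f1"))
  # classes are fully separable: perfect accuracy with zero spread
  expect_equal(cv$summary$mean[1], 1)
  expect_equal(cv$summary$sd[1], 0)
})

test_that("McNemar test uses continuity-corrected discordant counts", {
  # b = 15, c = 5: statistic (|15-5|-1)^2/20 = 4.05
  truth <- rep(1L, 40)
  pred_a <- c(rep(1L, 15), rep(2L, 5), rep(1L, 10), rep(2L, 10))
  pred_b <- c(rep(2L, 15), rep(1L, 5), rep(1L, 10), rep(2L, 10))
  m <- mcnemarTest(pred_a, pred_b, truth)
  expect_identical(m$b, 15L)
  expect_identical(m$c, 5L)
  expect_equal(m$statistic, 4.05)
  expect_equal(m$p_value, pchisq(4.05, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(m$p_value, 0.0442, tolerance = 1e-3)
  # symmetric discordance: weak evidence
  pred_c <- c(rep(2L, 5), rep(1L, 25), rep(2L, 10))
  ms <- mcnemarTest(pred_a, pred_c, truth)
  expect_identical(ms$b, ms$c)
  expect_lt(ms$statistic, 1)
  expect_gt(ms$p_value, 0.3)
  # identical predictions are indistinguishable
  expect_identical(mcnemarTest(pred_a, pred_a, truth)$p_value, 1)
  expect_error(mcnemarTest(pred_a, pred_b, truth[-1]), "equal length")
})

test_that("McNemar matches the stats implementation on random predictions", {
  set.seed(35)
  truth <- sample(1:3, 200, replace = TRUE)
  pa <- ifelse(runif(200) < 0.7, truth, sample(1:3, 200, replace = TRUE))
  pb <- ifelse(runif(200) < 0.6, truth, sample(1:3, 200, replace = TRUE))
  m <- mcnemarTest(pa, pb, truth)
  tab <- table(factor(pa == truth, c(TRUE, FALSE)),
               factor(pb == truth, c(TRUE, FALSE)))
  ref <- stats::mcnemar.test(tab, correct = TRUE)
  expect_equal(m$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(m$p_value, unname(ref$p.value), tolerance = 1e-12)
})
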