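test_that("inertia weight decays linearly from 1 to 0", {
  expect_identical(inertiaWeight(25, 50), 0.5)
  expect_identical(inertiaWeight(50, 50), 0)
  expect_identical(inertiaWeight(0, 50), 1)
  expect_equal(inertiaWeight(1, 50), 0.98)
  expect_error(inertiaWeight(51, 50), "max_iters")
})

test_that("sigmoid transfer is the logistic function", {
  expect_identical(transferSigmoid(0), 0.5)
  # independent oracle: stats::plogis
  v <- c(-3, -1, 0.5, 2, 6)
  expect_equal(transferSigmoid(v), stats::plogis(v), tolerance = 1e-15)
  expect_equal(transferSigmoid(2), 0.880797, tolerance = 1e-6)
  expect_true(all(diff(transferSigmoid(seq(-10, 10, 0.1))) > 0))
  expect_equal(transferSigmoid(50), 1, tolerance = 1e-12)
})

test_that("binarisation thresholds a uniform draw against the sigmoid", {
  expect_identical(binarizeVelocity(0, rand = 0.4), 1L)
  expect_identical(binarizeVelocity(0, rand = 0.6), 0L)
  # saturation: at v = -50 a one is (almost) impossible
  set.seed(42)
  draws <- binarizeVelocity(rep(-50, 1e4))
  expect_lte(sum(draws), 1L)
  set.seed(42)
  expect_gte(sum(binarizeVelocity(rep(50, 1e4))), 1e4 - 1L)
})

test_that("velocity update follows the inertia + attraction form and clamps", {
  # attraction terms vanish when x == pbest == gbest
  x <- c(1, 0, 1)
  v <- c(0.3, -0.2, 0.5)
  expect_equal(updateVelocity(v, x, x, x, w = 0.7), 0.7 * v)
  # pinned hand evaluation: 0.5*1 + 1*0.5*1 + 1*0.5*0 = 1
  expect_equal(updateVelocity(1, 0, 1, 0, w = 0.5, r1 = 0.5, r2 = 0.5), 1.0)
  # zero velocity at the consensus point is a fixed point
  expect_equal(updateVelocity(c(0, 0, 0), x, x, x, w = 0.9), c(0, 0, 0))
  # clamping
  expect_equal(updateVelocity(10, 0, 1, 1, w = 1, r1 = 1, r2 = 1, clamp = 6), 6)
  expect_error(updateVelocity(c(1, 2), c(0, 1, 0), c(1, 1, 0), c(0, 0, 0), 1),
               "dimensions")
})

test_that("reduction term is the discarded fraction of the feature space", {
  expect_identical(reductionTerm(592, 1280), 0.5375)
  expect_identical(reductionTerm(1280, 1280), 0)
  expect_identical(reductionTerm(0, 1280), 1)
  expect_error(reductionTerm(9, 8), "full_dim")
})

test_that("fitness combines embedded-KNN accuracy with feature reduction", {
  pf <- planted_small()
  fitc <- fitnessConfig(8L)
  # perfectly separable data, all-ones mask: eta = 1, delta = 0 -> 0.99
  expect_identical(subsetFitness(rep(1L, 8), pf$train, pf$val, fitc), 0.99)
  # omega = 1 disables the reduction term: F == eta for any mask
  mask <- c(1L, 0L, 1L, 1L, 0L, 0L, 1L, 0L)
  eta <- mean(knnClassify(
    featureValues(pf$train)[, mask == 1L, drop = FALSE],
    featureValues(pf$val)[, mask == 1L, drop = FALSE],
    k = 6, train_labels = sampleLabels(pf$train)) == sampleLabels(pf$val))
  expect_identical(subsetFitness(mask, pf$train, pf$val, fitnessConfig(8L, omega = 1)),
                   eta)
  # measured eta composes with delta by the weighted sum
  half <- c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L)
  eta_half <- mean(knnClassify(
    featureValues(pf$train)[, 1:4], featureValues(pf$val)[, 1:4],
    k = 6, train_labels = sampleLabels(pf$train)) == sampleLabels(pf$val))
  expect_equal(subsetFitness(half, pf$train, pf$val, fitc),
               0.99 * eta_half + 0.01 * 0.5, tolerance = 1e-12)
  # the empty mask sits at the fitness floor
  expect_identical(subsetFitness(rep(0L, 8), pf$train, pf$val, fitc), 0)
  expect_error(subsetFitness(rep(1L, 7), pf$train, pf$val, fitc), "agree")
})

test_that("optimiser runs are reproducible and monotone in global best", {
  pf <- planted_small()
  swarm <- swarmConfig(pop_size = 8L, max_iters = 10L, n_runs = 2L, seed = 9L)
  fitc <- fitnessConfig(8L)
  r1 <- runBPSO(pf$train, pf$val, swarm, fitc)
  r2 <- runBPSO(pf$train, pf$val, swarm, fitc)
  expect_identical(selectionMask(r1), selectionMask(r2))
  expect_identical(gbestHistory(r1), gbestHistory(r2))
  expect_identical(r1@runs, r2@runs)
  for (run in r1@runs) expect_false(is.unsorted(run$history))
  expect_length(gbestHistory(r1), 11L)
  expect_identical(r1@n_selected, sum(selectionMask(r1)))
})

test_that("a seeded all-ones particle can only be improved upon", {
  pf <- planted_small()
  res <- runBPSO(pf$train, pf$val,
                 swarmConfig(pop_size = 6L, max_iters = 10L, n_runs = 1L,
                             seed = 2L),
                 fitnessConfig(8L), init_positions = matrix(1L, 1L, 8L))
  all_ones_fit <- subsetFitness(rep(1L, 8), pf$train, pf$val, fitnessConfig(8L))
  expect_gte(gbestHistory(res)[1L], all_ones_fit)
  expect_gte(bestFitness(res), all_ones_fit)
})

test_that("single-class training data is refused", {
  vals <- matrix(rnorm(40), 10, 4)
  one <- FeatureMatrix(vals, rep(1L, 10), "train")
  expect_error(runBPSO(one, one, swarmConfig(n_runs = 1L),
                       fitnessConfig(4L)), "two classes")
})

test_that("exhaustive oracle finds planted singletons and refuses large spaces", {
  # D = 1: the only non-empty subset
  set.seed(13)
  v1 <- matrix(c(rnorm(10, 0), rnorm(10, 6)), ncol = 1)
  fm1 <- FeatureMatrix(v1, rep(1:2, each = 10), "train")
  ex1 <- exhaustiveSearch(fm1, fm1, fitnessConfig(1L))
  expect_identical(ex1$mask, 1L)
  # D = 3, one perfectly predictive column among pure noise: the singleton
  # on that column maximises delta at eta = 1
  set.seed(14)
  n <- 30
  y <- rep(1:2, each = n / 2)
  vals <- cbind(ifelse(y == 1, -5, 5) + rnorm(n, sd = 0.1),
                rnorm(n), rnorm(n))
  tr <- FeatureMatrix(vals[seq(1, n, 2), ], y[seq(1, n, 2)], "train")
  ev <- FeatureMatrix(vals[seq(2, n, 2), ], y[seq(2, n, 2)], "val")
  ex3 <- exhaustiveSearch(tr, ev, fitnessConfig(3L))
  expect_identical(ex3$mask, c(1L, 0L, 0L))
  expect_error(exhaustiveSearch(
    FeatureMatrix(matrix(rnorm(42), 2), rep(1:2, 1), "train"),
    FeatureMatrix(matrix(rnorm(42), 2), rep(1:2, 1), "val"),
    fitnessConfig(21L)), "refuses")
})

test_that("writeFSResult round-trips the selection result", {
  pf <- planted_small()
  res <- runBPSO(pf$train, pf$val,
                 swarmConfig(pop_size = 5L, max_iters = 5L, n_runs = 2L,
                             seed = 4L), fitnessConfig(8L))
  f <- tempfile(fileext = ".json")
  writeFSResult(res, f)
  back <- readFSResult(f)
  expect_identical(selectionMask(back), selectionMask(res))
  expect_equal(bestFitness(back), bestFitness(res), tolerance = 1e-12)
  expect_equal(gbestHistory(back), gbestHistory(res), tolerance = 1e-12)
})
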