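test_that("extraction taps FC-2: one row per image, fc2_units wide, deterministic", {
  run <- smoke_run()
  ck <- checkpoints(run$snapshots)[[1]]
  ds_n <- 6L
  set.seed(21)
  x <- array(runif(32 * 32 * 1 * ds_n), c(32, 32, 1, ds_n))
  fm <- extractFeatures(ck, x, rep(1:3, each = 2), split = "val")
  expect_identical(featureDim(fm), 32L)           # fc2_units of the preset
  expect_identical(ncol(fm), ds_n)
  expect_identical(splitTag(fm), "val")
  expect_true(all(snapshotBlocks(fm) == 1L))
  # determinism: extracting twice gives identical matrices
  fm2 <- extractFeatures(ck, x, rep(1:3, each = 2), split = "val")
  expect_identical(featureValues(fm), featureValues(fm2))
  # empty input yields a 0-row matrix of full width
  fm0 <- extractFeatures(ck, x[, , , 0, drop = FALSE], integer(0))
  expect_identical(dim(featureValues(fm0)), c(0L, 32L))
})

test_that("fusion concatenates snapshot blocks and is width-additive", {
  mk <- function(w, labels = c(1L, 1L, 2L), blk = 1L, split = "train")
    FeatureMatrix(matrix(seq_len(3 * w), 3, w), labels, split,
                  blocks = rep(blk, w))
  ms <- list(mk(4, blk = 1L), mk(3, blk = 2L), mk(5, blk = 3L))
  fused <- fuseFeatures(ms)
  expect_identical(featureDim(fused), 12L)
  expect_identical(snapshotBlocks(fused), rep(1:3, c(4L, 3L, 5L)))
  expect_identical(sampleLabels(fused), c(1L, 1L, 2L))
  # column order preserves snapshot order
  expect_identical(featureValues(fused)[, 1:4], featureValues(ms[[1]]))
  # single matrix is the identity
  expect_identical(fuseFeatures(ms[1]), ms[[1]])
  # misalignment guards
  bad_rows <- FeatureMatrix(matrix(1:8, 2, 4), c(1L, 2L), "train")
  expect_error(fuseFeatures(list(mk(4), bad_rows)), "row counts")
  bad_labels <- mk(4, labels = c(2L, 1L, 2L))
  expect_error(fuseFeatures(list(mk(4), bad_labels)), "labels")
  bad_split <- mk(4, split = "test")
  expect_error(fuseFeatures(list(mk(4), bad_split)), "split")
})

test_that("five snapshot matrices of width 256 fuse to width 1280", {
  mk256 <- function(blk) FeatureMatrix(matrix(rnorm(2 * 256), 2, 256),
                                       c(1L, 2L), blocks = rep(blk, 256L))
  set.seed(3)
  fused <- fuseFeatures(lapply(1:5, mk256))
  expect_identical(featureDim(fused), 1280L)
})

test_that("top-k snapshot selection ranks by accuracy, ties to earlier index", {
  # published fold-1 snapshot accuracies
  expect_identical(selectTopSnapshots(c(94.80, 96.40, 95.60, 96.60, 95.80), 2L),
                   c(2L, 4L))
  expect_identical(selectTopSnapshots(c(94.80, 96.40, 95.60, 96.60, 95.80), 5L),
                   1:5)
  expect_identical(selectTopSnapshots(c(0.9, 0.9, 0.8), 1L), 1L)
  expect_identical(selectTopSnapshots(c(0.8, 0.9, 0.9), 2L), 2:3)
  expect_error(selectTopSnapshots(c(0.9, 0.8), 3L), "between")
  expect_error(selectTopSnapshots(c(0.9, 0.8), 0L), "between")
})

test_that("CSV round trip preserves values, labels, blocks and split", {
  set.seed(8)
  fm <- FeatureMatrix(matrix(rnorm(5 * 7), 5, 7), c(1L, 2L, 1L, 2L, 1L),
                      split = "test", blocks = c(1L, 1L, 1L, 2L, 2L, 3L, 3L))
  f <- tempfile(fileext = ".csv")
  writeFeatureCSV(fm, f)
  back <- readFeatureCSV(f)
  expect_equal(featureValues(back), featureValues(fm), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_identical(sampleLabels(back), sampleLabels(fm))
  expect_identical(snapshotBlocks(back), snapshotBlocks(fm))
  expect_identical(splitTag(back), "test")
})

test_that("train and test matrices from one run carry disjoint sample ids", {
  run <- smoke_run()
  ids <- function(fm) SummarizedExperiment::colData(fm)$sample_id
  expect_length(intersect(ids(run$fused$train), ids(run$fused$test)), 0L)
  expect_length(intersect(ids(run$fused$train), ids(run$fused$val)), 0L)
})

test_that("non-finite feature values are rejected", {
  expect_error(FeatureMatrix(matrix(c(1, NA, 3, 4), 2, 2), c(1L, 2L)),
               "finite")
})
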