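test_that("texture datasets are balanced, sized and seed-reproducible", {
  spec <- textureSpec(num_classes = 3L, per_class = 40L, image_size = 32L,
                      seed = 5L)
  ds <- makeTextureDataset(spec)
  expect_identical(dim(ds$images), c(32L, 32L, 1L, 120L))
  expect_identical(as.vector(table(ds$labels)), rep(40L, 3L))
  expect_true(all(ds$images >= 0 & ds$images <= 1))
  ds2 <- makeTextureDataset(spec)
  expect_identical(ds$images, ds2$images)
  expect_identical(ds$splits, ds2$splits)
  # split manifest partitions the samples
  all_idx <- sort(unname(unlist(ds$splits)))
  expect_identical(all_idx, seq_len(120L))
})

test_that("degenerate class parameters are rejected", {
  expect_error(textureSpec(num_classes = 2L, frequencies = c(3, 3),
                           orientations = c(0, 0), blob_density = c(0, 0)),
               "distinct")
  expect_error(textureSpec(region = "left-half"), "region")
})

test_that("class-mean power spectra peak at the planted grating frequencies", {
  freqs <- c(3, 6, 9)
  ds <- makeTextureDataset(textureSpec(
    num_classes = 3L, per_class = 10L, image_size = 32L,
    frequencies = freqs, orientations = c(0, 0, 0),
    blob_density = c(0, 0, 0), noise_sd = 0, seed = 6L))
  for (cl in 1:3) {
    idx <- which(ds$labels == cl)
    pw <- Reduce(`+`, lapply(idx, function(i)
      Mod(fft(ds$images[, , 1, i] - mean(ds$images[, , 1, i])))^2))
    peak <- which(pw == max(pw), arr.ind = TRUE)[1, ]
    # orientation 0 varies along columns: peak at column bin f (0-based),
    # possibly its mirror
    expect_identical(unname(peak["row"]), 1L)
    expect_true(unname(peak["col"]) %in% (c(freqs[cl], 32 - freqs[cl]) + 1L))
  }
})

test_that("planted feature matrices keep their block bookkeeping", {
  spec <- plantedFeatureSpec(num_classes = 3L, samples_per_class = 20L,
                             n_informative = 3L, n_redundant = 4L,
                             n_noise = 5L, seed = 9L)
  pf <- makePlantedFeatures(spec)
  expect_identical(ncol(pf$values), 12L)
  expect_identical(sum(pf$truth_mask), 3L)
  expect_identical(as.vector(table(pf$column_type)), c(3L, 4L, 5L))
  expect_identical(as.vector(table(pf$labels)), rep(20L, 3L))
  # split rows are disjoint and cover everything
  n_split <- sum(ncol(pf$train), ncol(pf$val), ncol(pf$test))
  expect_identical(n_split, 60L)
  pf2 <- makePlantedFeatures(spec)
  expect_identical(pf$values, pf2$values)
  expect_error(plantedFeatureSpec(n_informative = 0L), "informative")
})

test_that("informative columns separate classes; permuted labels collapse to chance", {
  pf <- planted_sep()   # wide separation, small noise
  inf_cols <- which(pf$truth_mask == 1L)
  expect_equal(knn_holdout_accuracy(pf, inf_cols), 1.0)
  # permutation null: accuracy near 1/num_classes
  set.seed(10)
  perm <- sample(sampleLabels(pf$train))
  pred <- knnClassify(featureValues(pf$train)[, inf_cols],
                      featureValues(pf$test)[, inf_cols],
                      k = 6, train_labels = perm)
  expect_lt(mean(pred == sampleLabels(pf$test)), 0.25 + 0.15)
})

test_that("the ground-truth mask is at least as fit as selecting everything", {
  pf <- planted_small()
  fitc <- fitnessConfig(8L)
  expect_gte(subsetFitness(pf$truth_mask, pf$train, pf$val, fitc),
             subsetFitness(rep(1L, 8), pf$train, pf$val, fitc))
})
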