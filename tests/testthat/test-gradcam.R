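test_that("activation maps satisfy the shape, range and normalisation contract", {
  snaps <- quadrant_snapshots()
  ds <- quadrant_data()
  ck <- checkpoints(snaps)[[5]]
  i <- ds$splits$test[1]
  am <- gradCAM(ck, ds$images[, , 1, i], ds$labels[i])
  expect_s4_class(am, "ActivationMap")
  expect_identical(dim(am@heat), c(32L, 32L))
  expect_true(all(am@heat >= 0 & am@heat <= 1))
  expect_equal(max(am@heat), 1)   # positive evidence survives, so max is 1
  expect_identical(am@snapshot_index, 5L)
  # determinism
  am2 <- gradCAM(ck, ds$images[, , 1, i], ds$labels[i])
  expect_identical(am@heat, am2@heat)
})

test_that("heat concentrates in the quadrant carrying the class texture", {
  snaps <- quadrant_snapshots()
  ds <- quadrant_data()
  ck <- checkpoints(snaps)[[5]]
  test_idx <- ds$splits$test[1:10]
  inside_wins <- vapply(test_idx, function(i) {
    am <- gradCAM(ck, ds$images[, , 1, i], ds$labels[i])
    mean(am@heat[ds$region_mask]) > mean(am@heat[!ds$region_mask])
  }, logical(1))
  expect_gte(sum(inside_wins), 8L)
})

test_that("an all-negative map degrades to zeros with a warning", {
  snaps <- quadrant_snapshots()
  ds <- quadrant_data()
  ck <- checkpoints(snaps)[[5]]
  ck@head$W3[] <- 0   # no class evidence reaches the logits
  ck@head$b3[] <- 0
  expect_warning(am <- gradCAM(ck, ds$images[, , 1, ds$splits$test[1]], 1L),
                 "zero map")
  expect_true(all(am@heat == 0))
})

test_that("invalid class indices are rejected", {
  snaps <- quadrant_snapshots()
  ds <- quadrant_data()
  expect_error(gradCAM(checkpoints(snaps)[[1]], ds$images[, , 1, 1], 4L),
               "range")
})

test_that("overlay blends image and colour-mapped heat by alpha", {
  set.seed(41)
  img <- array(runif(16 * 16), c(16, 16, 1))
  heat <- matrix(runif(16 * 16), 16, 16)
  am <- new("ActivationMap", heat = heat, class_index = 1L,
            snapshot_index = 1L)
  gray3 <- array(rep(img[, , 1], 3), c(16, 16, 3))
  expect_equal(overlayHeatmap(img, am, alpha = 0), gray3)
  # alpha = 1 is the pure heat rendering: independent of the image
  o1 <- overlayHeatmap(img, am, alpha = 1)
  o2 <- overlayHeatmap(array(0.2, c(16, 16, 1)), am, alpha = 1)
  expect_identical(o1, o2)
  o5 <- overlayHeatmap(img, am, alpha = 0.5)
  expect_true(all(o5 >= 0 & o5 <= 1))
  # deterministic rendering: byte-identical PNG exports
  f1 <- tempfile(fileext = ".png"); f2 <- tempfile(fileext = ".png")
  writeImagePNG(o5, f1); writeImagePNG(overlayHeatmap(img, am, 0.5), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  bad <- new("ActivationMap", heat = matrix(0, 8, 8), class_index = 1L,
             snapshot_index = 1L)
  expect_error(overlayHeatmap(img, bad, 0.5), "shapes")
  expect_error(overlayHeatmap(img, am, 1.5), "alpha")
})
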