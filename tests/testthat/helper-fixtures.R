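# Shared fixtures, built once per test run and cached. Everything is
# generated in code from fixed seeds; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, make(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# Small planted feature set (D = 8) for oracle/optimiser benchmarks.
planted_small <- function() fixture("planted_small", function()
  makePlantedFeatures(plantedFeatureSpec(
    num_classes = 3L, samples_per_class = 30L, n_informative = 2L,
    n_redundant = 3L, n_noise = 3L, class_separation = 4, seed = 5L)))

# Default planted benchmark (4 informative, 8 redundant, 52 noise,
# 4 classes x 60 samples).
planted_bench <- function() fixture("planted_bench", function()
  makePlantedFeatures(plantedFeatureSpec(seed = 1L)))

# Widely separated classes with little noise: perfectly separable by
# construction.
planted_sep <- function() fixture("planted_sep", function()
  makePlantedFeatures(plantedFeatureSpec(
    num_classes = 4L, samples_per_class = 30L, n_informative = 3L,
    n_redundant = 0L, n_noise = 2L, class_separation = 10,
    noise_sd = 0.5, seed = 6L)))

# Desk-scale end-to-end run: tiny backbone on 3-class 32x32 textures,
# 10 epochs in 5 cycles.
smoke_run <- function() fixture("smoke_run", function()
  runPipeline(pipelinePreset("smoke"),
              out_dir = file.path(tempdir(), "smoke_run")))

# Independent repetition of the same configuration in a fresh directory,
# for reproducibility checks.
smoke_run_repeat <- function() fixture("smoke_run_repeat", function()
  runPipeline(pipelinePreset("smoke"),
              out_dir = file.path(tempdir(), "smoke_run_repeat")))

# Textures whose class-discriminative grating lives in the top-left
# quadrant, plus snapshots trained on them (for localisation tests).
quadrant_data <- function() fixture("quadrant_data", function()
  makeTextureDataset(textureSpec(
    num_classes = 3L, per_class = 40L, image_size = 32L, channels = 1L,
    noise_sd = 0.05, region = "q1", seed = 7L)))

quadrant_snapshots <- function() fixture("quadrant_snapshots", function() {
  ds <- quadrant_data()
  tc <- trainConfig("tiny_cnn", num_classes = 3L, fc1_units = 64L,
                    fc2_units = 32L, image_size = 32L, channels = 1L,
                    batch_size = 16L, seed = 2L,
                    schedule = scheduleConfig(0.05, 10L, 5L))
  trainSnapshots(buildModel(tc),
                 ds$images[, , , ds$splits$train, drop = FALSE],
                 ds$labels[ds$splits$train],
                 ds$images[, , , ds$splits$val, drop = FALSE],
                 ds$labels[ds$splits$val])
})

# Tiny train config for fast degenerate-case runs.
tiny_config <- function(epochs = 2L, cycles = 1L, seed = 3L,
                        num_classes = 2L)
  trainConfig("tiny_cnn", num_classes = num_classes, fc1_units = 16L,
              fc2_units = 8L, image_size = 8L, channels = 1L,
              batch_size = 4L, seed = seed,
              schedule = scheduleConfig(0.05, epochs, cycles))

# Minimal labelled image batch for the tiny config.
tiny_batch <- function(n = 8L, num_classes = 2L, seed = 4L) {
  set.seed(seed)
  list(x = array(runif(8 * 8 * 1 * n), c(8L, 8L, 1L, n)),
       y = rep_len(seq_len(num_classes), n))
}

knn_holdout_accuracy <- function(pf, cols, k = 6L) {
  pred <- knnClassify(featureValues(pf$train)[, cols, drop = FALSE],
                      featureValues(pf$test)[, cols, drop = FALSE],
                      k = k, train_labels = sampleLabels(pf$train))
  mean(pred == sampleLabels(pf$test))
}
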