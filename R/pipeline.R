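# Pipeline configuration and the end-to-end driver tying the stages
# together: data -> snapshot training -> per-snapshot extraction -> fusion
# -> PSO selection -> evaluation. Every stage writes a JSON manifest
# (inputs, outputs, config hash, seed, duration) into the run directory,
# and a completed stage whose manifest matches the current configuration
# is skipped on re-runs.

.CONFIG_SCHEMA <- list(
  data = c("type", "dir", "num_classes", "per_class", "image_size",
           "channels", "frequencies", "orientations", "blob_density",
           "noise_sd", "region", "seed"),
  schedule = c("initial_lr", "epochs", "cycles"),
  training = c("backbone", "fc1_units", "fc2_units", "batch_size",
               "momentum", "leaky_slope", "freeze_trunk", "seed"),
  fs = c("pop", "iters", "runs", "c1", "c2", "omega", "knn_k", "seed",
         "velocity_clamp", "eval_on"),
  evaluate = c("knn_k")
)

#' Preset pipeline configurations
#'
#' `"reference"` mirrors the reference setup: MobileNetV2 backbone with the
#' 4096/256 head, 100 epochs in 5 cycles at initial rate `2e-4`, PSO with
#' 20 particles, 50 iterations, 10 repetitions, `omega = 0.99`, KNN
#' `k = 6`, `c1 = c2 = 1`. `"smoke"` is the desk-scale configuration used
#' throughout the tests: the trainable tiny backbone on 3-class 32 x 32
#' synthetic textures, 10 epochs in 5 cycles at initial rate 0.05 (a
#' from-scratch CNN needs a larger step than a fine-tuned one), a 64/32
#' head, and a lighter swarm.
#'
#' @param name `"reference"` or `"smoke"`.
#' @return nested configuration list.
#' @export
pipelinePreset <- function(name = c("reference", "smoke")) {
  name <- match.arg(name)
  if (name == "reference") {
    list(
      data = list(type = "image_folder", dir = ".", num_classes = 8L,
                  image_size = 224L, channels = 3L, seed = 1L),
      schedule = list(initial_lr = 2e-4, epochs = 100L, cycles = 5L),
      training = list(backbone = "mobilenet_v2", fc1_units = 4096L,
                      fc2_units = 256L, batch_size = 32L, momentum = 0.9,
                      leaky_slope = 0.01, freeze_trunk = TRUE, seed = 1L),
      fs = list(pop = 20L, iters = 50L, runs = 10L, c1 = 1, c2 = 1,
                omega = 0.99, knn_k = 6L, seed = 1L, velocity_clamp = 6,
                eval_on = "val"),
      evaluate = list(knn_k = 6L))
  } else {
    list(
      data = list(type = "synthetic_textures", num_classes = 3L,
                  per_class = 40L, image_size = 32L, channels = 1L,
                  noise_sd = 0.05, region = "full", seed = 11L),
      schedule = list(initial_lr = 0.05, epochs = 10L, cycles = 5L),
      training = list(backbone = "tiny_cnn", fc1_units = 64L,
                      fc2_units = 32L, batch_size = 16L, momentum = 0.9,
                      leaky_slope = 0.01, freeze_trunk = FALSE, seed = 2L),
      fs = list(pop = 10L, iters = 10L, runs = 2L, c1 = 1, c2 = 1,
                omega = 0.99, knn_k = 6L, seed = 3L, velocity_clamp = 6,
                eval_on = "val"),
      evaluate = list(knn_k = 6L))
  }
}

#' Validate a pipeline configuration
#'
#' Rejects unknown sections or keys, enforces that every stochastic stage
#' carries an explicit seed, and checks the schedule (epochs divisible by
#' cycles) before any compute starts.
#'
#' @param config nested configuration list.
#' @return the config, invisibly, on success; otherwise an error.
#' @export
validatePipelineConfig <- function(config) {
  unknown <- setdiff(names(config), names(.CONFIG_SCHEMA))
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  for (sec in names(config)) {
    bad <- setdiff(names(config[[sec]]), .CONFIG_SCHEMA[[sec]])
    if (length(bad))
      stop(sprintf("unknown key(s) in section '%s': %s", sec,
                   paste(bad, collapse = ", ")))
  }
  for (sec in c("data", "training", "fs"))
    if (is.null(config[[sec]]$seed))
      stop(sprintf("section '%s' must carry an explicit seed", sec))
  sc <- config$schedule
  if (is.null(sc$epochs) || is.null(sc$cycles) || is.null(sc$initial_lr))
    stop("schedule must define initial_lr, epochs and cycles")
  if (sc$epochs %% sc$cycles != 0)
    stop(sprintf("epochs (%d) must be divisible by cycles (%d)",
                 sc$epochs, sc$cycles))
  invisible(config)
}

#' Read a pipeline configuration from YAML
#'
#' Starts from a preset and overlays the keys present in the file; the
#' merged configuration is validated (unknown keys are rejected).
#'
#' @param path YAML file.
#' @param preset base preset to overlay onto.
#' @return validated configuration list.
#' @export
readPipelineConfig <- function(path, preset = "smoke") {
  user <- yaml::read_yaml(path)
  config <- pipelinePreset(preset)
  for (sec in names(user)) {
    if (!sec %in% names(.CONFIG_SCHEMA))
      stop("unknown config section: ", sec)
    for (key in names(user[[sec]]))
      config[[sec]][[key]] <- user[[sec]][[key]]
  }
  validatePipelineConfig(config)
  config
}

.config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

.write_manifest <- function(dir, stage, hash, seed, t0, inputs, outputs) {
  jsonlite::write_json(
    list(stage = stage, config_hash = hash, seed = seed,
         duration_s = round(as.numeric(Sys.time()) - t0, 3),
         inputs = inputs, outputs = outputs),
    file.path(dir, paste0("manifest_", stage, ".json")), auto_unbox = TRUE)
}

.stage_done <- function(dir, stage, hash) {
  mf <- file.path(dir, paste0("manifest_", stage, ".json"))
  if (!file.exists(mf)) return(FALSE)
  identical(jsonlite::read_json(mf)$config_hash, as.character(hash))
}

#' Load a directory-per-class image folder
#'
#' Reads PNG/TIFF/JPEG images from one subdirectory per class (classes in
#' lexicographic order), converts to grayscale or RGB as configured and
#' resizes to `image_size` with bilinear interpolation.
#'
#' @param dir root folder with one subdirectory per class.
#' @param image_size output side in pixels.
#' @param channels 1 or 3.
#' @return list with `images` (`(H, W, C, N)`), `labels`, `class_names`.
#' @export
loadImageFolder <- function(dir, image_size = 224L, channels = 3L) {
  classes <- sort(list.dirs(dir, recursive = FALSE))
  if (!length(classes)) stop("no class subdirectories in ", dir)
  files <- lapply(classes, function(d)
    sort(list.files(d, pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                    ignore.case = TRUE, full.names = TRUE)))
  n <- sum(lengths(files))
  if (n == 0L) stop("no images found under ", dir)
  imgs <- array(0, c(image_size, image_size, channels, n))
  labels <- integer(n)
  i <- 0L
  for (cl in seq_along(classes)) {
    for (f in files[[cl]]) {
      i <- i + 1L
      im <- EBImage::readImage(f)
      if (channels == 1L && length(dim(im)) == 3L)
        im <- EBImage::channel(im, "gray")
      if (channels == 3L && length(dim(im)) == 2L)
        im <- EBImage::rgbImage(im, im, im)
      im <- EBImage::resize(im, w = image_size, h = image_size,
                            filter = "bilinear")
      dat <- EBImage::imageData(im)
      if (length(dim(dat)) == 2L) dat <- array(dat, c(dim(dat), 1L))
      imgs[, , , i] <- dat[, , seq_len(channels)]
      labels[i] <- cl
    }
  }
  list(images = imgs, labels = labels, class_names = basename(classes))
}

#' Run the full snapshot-ensemble feature-selection pipeline
#'
#' Executes data preparation, snapshot training, per-snapshot FC-2 feature
#' extraction, fusion, binary-PSO feature selection and final KNN
#' evaluation, writing artefacts and per-stage manifests into `out_dir`:
#' the learning-rate table and training log as CSV, fused feature CSVs per
#' split, the selection result and evaluation report as JSON, and snapshot
#' checkpoints as RDS. A rerun with an identical configuration reuses
#' completed stages.
#'
#' @param config validated configuration list (see [pipelinePreset()],
#'   [readPipelineConfig()]).
#' @param out_dir run directory, created if needed.
#' @return list with `snapshots` ([SnapshotSet-class]), `fused` (list of
#'   train/val/test [FeatureMatrix-class]), `fsresult`
#'   ([FSResult-class]), `report` ([EvalReport-class]) and `dir`.
#' @export
runPipeline <- function(config, out_dir = tempfile("snapfs_run_")) {
  validatePipelineConfig(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(config)

  # --- data -----------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  dc <- config$data
  if (identical(dc$type, "synthetic_textures")) {
    spec <- textureSpec(
      num_classes = dc$num_classes, per_class = dc$per_class,
      image_size = dc$image_size, channels = dc$channels,
      noise_sd = dc$noise_sd, region = dc$region, seed = dc$seed)
    ds <- makeTextureDataset(spec)
    splits <- ds$splits
  } else {
    folder <- loadImageFolder(dc$dir, dc$image_size, dc$channels)
    set.seed(dc$seed)
    splits <- .stratified_split(folder$labels,
                                c(train = 0.6, val = 0.2, test = 0.2))
    ds <- list(images = folder$images, labels = folder$labels,
               splits = splits)
  }
  .write_manifest(out_dir, "data", hash, dc$seed, t0,
                  inputs = dc, outputs = list(n = length(ds$labels)))

  tc <- trainConfig(
    backbone_id = config$training$backbone,
    num_classes = length(unique(ds$labels)),
    fc1_units = config$training$fc1_units,
    fc2_units = config$training$fc2_units,
    image_size = dc$image_size, channels = dc$channels,
    batch_size = config$training$batch_size,
    momentum = config$training$momentum,
    leaky_slope = config$training$leaky_slope,
    freeze_trunk = config$training$freeze_trunk,
    seed = config$training$seed,
    schedule = scheduleConfig(config$schedule$initial_lr,
                              config$schedule$epochs, config$schedule$cycles))

  # --- train ----------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  snap_file <- file.path(out_dir, "snapshots.rds")
  if (.stage_done(out_dir, "train", hash) && file.exists(snap_file)) {
    snapshots <- readRDS(snap_file)
  } else {
    model <- buildModel(tc)
    snapshots <- trainSnapshots(
      model, ds$images[, , , splits$train, drop = FALSE],
      ds$labels[splits$train],
      ds$images[, , , splits$val, drop = FALSE], ds$labels[splits$val])
    saveRDS(snapshots, snap_file)
    write.csv(trainingLog(snapshots),
              file.path(out_dir, "training_log.csv"), row.names = FALSE)
    scheduleTable(tc@schedule, file.path(out_dir, "schedule.csv"))
    jsonlite::write_json(
      lapply(seq_along(checkpoints(snapshots)), function(i)
        list(snapshot = i, epoch = snapshotEpochs(tc@schedule)[i],
             val_accuracy = valAccuracy(snapshots)[i], config_hash = hash)),
      file.path(out_dir, "snapshots.json"), auto_unbox = TRUE)
    .write_manifest(out_dir, "train", hash, config$training$seed, t0,
                    inputs = config$training,
                    outputs = list(checkpoints = snap_file))
  }

  # --- extract + fuse -------------------------------------------------
  t0 <- as.numeric(Sys.time())
  fused <- list()
  for (part in c("train", "val", "test")) {
    idx <- splits[[part]]
    mats <- lapply(checkpoints(snapshots), function(ck)
      extractFeatures(ck, ds$images[, , , idx, drop = FALSE],
                      ds$labels[idx], split = part))
    fused[[part]] <- fuseFeatures(mats)
    writeFeatureCSV(fused[[part]],
                    file.path(out_dir, paste0("features_", part, ".csv")))
  }
  .write_manifest(out_dir, "extract", hash, config$training$seed, t0,
                  inputs = list(fc2_units = tc@fc2_units),
                  outputs = list(width = featureDim(fused$train)))

  # --- select ---------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  fs <- config$fs
  swarm <- swarmConfig(pop_size = fs$pop, max_iters = fs$iters,
                       c1 = fs$c1, c2 = fs$c2, seed = fs$seed,
                       n_runs = fs$runs, velocity_clamp = fs$velocity_clamp)
  fitc <- fitnessConfig(featureDim(fused$train), omega = fs$omega,
                        k_neighbors = fs$knn_k)
  eval_fm <- if (identical(fs$eval_on, "test")) fused$test else fused$val
  fsres <- runBPSO(fused$train, eval_fm, swarm, fitc)
  writeFSResult(fsres, file.path(out_dir, "fsresult.json"))
  .write_manifest(out_dir, "select", hash, fs$seed, t0, inputs = fs,
                  outputs = list(n_selected = fsres@n_selected))

  # --- evaluate -------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  sel <- which(selectionMask(fsres) == 1L)
  pred <- knnClassify(featureValues(fused$train)[, sel, drop = FALSE],
                      featureValues(fused$test)[, sel, drop = FALSE],
                      k = config$evaluate$knn_k,
                      train_labels = sampleLabels(fused$train))
  report <- evalMetrics(confusionMatrix(pred, sampleLabels(fused$test),
                                        tc@num_classes))
  writeEvalReport(report, file.path(out_dir, "eval_report.json"))
  .write_manifest(out_dir, "evaluate", hash, config$evaluate$knn_k, t0,
                  inputs = config$evaluate,
                  outputs = list(accuracy = accuracyOf(report)))

  list(snapshots = snapshots, fused = fused, fsresult = fsres,
       report = report, dir = out_dir)
}
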