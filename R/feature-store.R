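#' Construct a FeatureMatrix
#'
#' @param values numeric matrix, samples x features, all finite.
#' @param labels integer class labels (1-based), one per row of `values`.
#' @param split one of `"train"`, `"val"`, `"test"`.
#' @param blocks integer snapshot index of origin per feature column
#'   (default all 1).
#' @param sample_ids optional character identifiers; default `s1..sN` within
#'   the split (prefixed by the split tag so train/test identifiers are
#'   disjoint).
#' @return a [FeatureMatrix-class].
#' @export
FeatureMatrix <- function(values, labels, split = "train",
                          blocks = rep(1L, ncol(values)),
                          sample_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(sample_ids))
    sample_ids <- paste0(split, "_s", seq_len(nrow(values)), recycle0 = TRUE)
  if (nrow(values) != length(labels))
    stop("one label per sample row is required")
  if (ncol(values) != length(blocks))
    stop("one snapshot block id per feature column is required")
  assay <- t(values)
  rownames(assay) <- sprintf("f%04d", seq_len(nrow(assay)))
  colnames(assay) <- sample_ids
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = assay),
    rowData = S4Vectors::DataFrame(snapshot_block = as.integer(blocks)),
    colData = S4Vectors::DataFrame(label = as.integer(labels),
                                   sample_id = sample_ids),
    metadata = list(split_tag = split))
  new("FeatureMatrix", se)
}

#' Accessors for FeatureMatrix objects
#'
#' `featureValues()` returns the samples x features numeric matrix,
#' `sampleLabels()` the 1-based integer labels, `splitTag()` the split this
#' matrix belongs to, `snapshotBlocks()` the snapshot index of origin of
#' each feature column, and `featureDim()` the feature-space width.
#'
#' @param x a [FeatureMatrix-class].
#' @rdname FeatureMatrix-accessors
#' @export
setMethod("featureValues", "FeatureMatrix", function(x)
  t(SummarizedExperiment::assay(x, "features")))

#' @rdname FeatureMatrix-accessors
#' @export
setMethod("sampleLabels", "FeatureMatrix", function(x)
  SummarizedExperiment::colData(x)$label)

#' @rdname FeatureMatrix-accessors
#' @export
setMethod("splitTag", "FeatureMatrix", function(x)
  S4Vectors::metadata(x)$split_tag)

#' @rdname FeatureMatrix-accessors
#' @export
setMethod("snapshotBlocks", "FeatureMatrix", function(x)
  SummarizedExperiment::rowData(x)$snapshot_block)

#' @rdname FeatureMatrix-accessors
#' @export
setMethod("featureDim", "FeatureMatrix", function(x) nrow(x))

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d samples x %d features (%s split)\n",
              ncol(object), nrow(object), splitTag(object)))
  bl <- table(snapshotBlocks(object))
  cat("snapshot blocks:",
      paste(sprintf("#%s x%d", names(bl), as.integer(bl)), collapse = ", "),
      "\n")
})

#' Extract FC-2 deep features from a checkpoint
#'
#' Runs the images through the snapshot in evaluation mode (no training-time
#' stochasticity exists in this engine) and taps the FC-2 layer after its
#' leaky-ReLU activation, yielding one `fc2_units`-dimensional feature
#' vector per image. Extraction is deterministic: the same checkpoint and
#' inputs always give the identical matrix.
#'
#' @param checkpoint a [CNNModel-class] (typically one of
#'   `checkpoints(snapshotSet)`).
#' @param x image array `(H, W, C, N)`; `N = 0` is allowed and yields a
#'   0-row matrix of full width.
#' @param labels integer labels, one per image.
#' @param split split tag recorded on the result.
#' @param batch images processed per forward pass.
#' @return a [FeatureMatrix-class] of width `fc2_units`, with all columns
#'   tagged with the checkpoint's snapshot index.
#' @export
extractFeatures <- function(checkpoint, x, labels, split = "train",
                            batch = 64L) {
  cfg <- checkpoint@config
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  n <- dim(x)[4]
  if (n != length(labels)) stop("one label per image is required")
  vals <- matrix(0, n, cfg@fc2_units)
  if (n > 0L) for (start in seq(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    vals[idx, ] <- .model_forward(checkpoint, x[, , , idx, drop = FALSE])$features
  }
  blk <- max(checkpoint@snapshot_index, 1L)
  FeatureMatrix(vals, as.integer(labels), split = split,
                blocks = rep(blk, cfg@fc2_units))
}

#' Fuse per-snapshot feature matrices by column concatenation
#'
#' Stacks the feature vectors of each sample across snapshots, in the order
#' the matrices are given, so five 256-wide snapshot matrices fuse into one
#' 1280-wide matrix. All inputs must describe the same samples: equal row
#' counts, identical labels in identical order, and the same split tag —
#' a mismatch indicates misalignment or train/test leakage and is an error.
#'
#' @param matrices list of [FeatureMatrix-class] objects in snapshot order.
#' @return a [FeatureMatrix-class]; column provenance is kept in
#'   [snapshotBlocks()].
#' @export
fuseFeatures <- function(matrices) {
  if (!length(matrices)) stop("no matrices to fuse")
  if (length(matrices) == 1L) return(matrices[[1L]])
  ref_labels <- sampleLabels(matrices[[1L]])
  ref_split <- splitTag(matrices[[1L]])
  ref_ids <- SummarizedExperiment::colData(matrices[[1L]])$sample_id
  for (m in matrices[-1L]) {
    if (ncol(m) != length(ref_labels))
      stop("fusion error: row counts differ across snapshot matrices")
    if (!identical(sampleLabels(m), ref_labels))
      stop("fusion error: labels differ across snapshot matrices")
    if (!identical(splitTag(m), ref_split))
      stop("fusion error: split tags differ across snapshot matrices")
  }
  vals <- do.call(cbind, lapply(matrices, featureValues))
  blocks <- unlist(lapply(matrices, snapshotBlocks))
  FeatureMatrix(vals, ref_labels, split = ref_split, blocks = blocks,
                sample_ids = ref_ids)
}

#' Pick the k best-performing snapshots
#'
#' Ranks snapshots by validation accuracy and returns the indices of the
#' top `k`, in original snapshot (cycle) order — the ordering used for
#' top-k fusion ablations. Accuracy ties are broken in favour of the
#' earlier snapshot.
#'
#' @param snapshots a [SnapshotSet-class], or a numeric vector of
#'   per-snapshot validation accuracies.
#' @param k number of snapshots to keep, `1 <= k <= length(snapshots)`.
#' @return increasing integer vector of `k` snapshot indices.
#' @examples
#' selectTopSnapshots(c(94.8, 96.4, 95.6, 96.6, 95.8), k = 2)  # 2 4
#' @export
selectTopSnapshots <- function(snapshots, k) {
  acc <- if (is(snapshots, "SnapshotSet")) valAccuracy(snapshots)
         else as.numeric(snapshots)
  if (k < 1L || k > length(acc))
    stop("k must be between 1 and the number of snapshots")
  ord <- order(-acc, seq_along(acc))   # ties -> earlier snapshot index
  sort(ord[seq_len(k)])
}

#' Write / read a FeatureMatrix as CSV plus JSON sidecar
#'
#' The CSV holds the feature columns (`f0001..fNNNN`, 9 significant digits,
#' '.' decimal separator) and a final `label` column, one row per sample.
#' Per-column snapshot block ids, the split tag and sample identifiers go
#' to a JSON sidecar manifest at `<file>.json`, which `readFeatureCSV()`
#' requires. The round trip reproduces values to the printed precision,
#' labels and block ids exactly.
#'
#' @param fm a [FeatureMatrix-class].
#' @param file CSV path.
#' @return `writeFeatureCSV()` the path invisibly; `readFeatureCSV()` the
#'   reconstructed [FeatureMatrix-class].
#' @export
writeFeatureCSV <- function(fm, file) {
  vals <- featureValues(fm)
  df <- as.data.frame(signif(vals, 9))
  names(df) <- sprintf("f%04d", seq_len(ncol(vals)))
  df$label <- sampleLabels(fm)
  write.csv(df, file, row.names = FALSE)
  jsonlite::write_json(
    list(split_tag = splitTag(fm),
         snapshot_block = as.integer(snapshotBlocks(fm)),
         sample_id = SummarizedExperiment::colData(fm)$sample_id),
    paste0(file, ".json"), auto_unbox = TRUE)
  invisible(file)
}

#' @rdname writeFeatureCSV
#' @export
readFeatureCSV <- function(file) {
  df <- read.csv(file, check.names = FALSE)
  manifest <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  labels <- as.integer(df$label)
  vals <- as.matrix(df[, setdiff(names(df), "label"), drop = FALSE])
  FeatureMatrix(vals, labels, split = manifest$split_tag,
                blocks = manifest$snapshot_block,
                sample_ids = manifest$sample_id)
}
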