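#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats rnorm runif rbinom rpois setNames pchisq sd dist
#' @importFrom utils read.csv write.csv head tail
#' @importFrom tools md5sum
NULL

#' Cyclic cosine-annealing schedule parameters
#'
#' Holds the three parameters of the cyclic cosine-annealing learning-rate
#' schedule: the initial rate \eqn{\alpha_0}, the total number of training
#' epochs \eqn{E} and the number of cycles \eqn{C} into which training is
#' divided uniformly. \eqn{E} must be an exact multiple of \eqn{C}; uneven
#' cycle lengths are rejected rather than silently floored.
#'
#' @slot initial_rate positive numeric, learning rate at the start of each
#'   cycle (learning-rate units).
#' @slot total_epochs positive integer, total training epochs \eqn{E}.
#' @slot num_cycles positive integer, number of schedule cycles \eqn{C}.
#' @seealso [scheduleConfig()], [learningRate()], [snapshotEpochs()]
#' @export
setClass("ScheduleConfig",
  representation(
    initial_rate = "numeric",
    total_epochs = "integer",
    num_cycles   = "integer"
  )
)

setValidity("ScheduleConfig", function(object) {
  msg <- character()
  if (length(object@initial_rate) != 1L || !is.finite(object@initial_rate) ||
      object@initial_rate <= 0)
    msg <- c(msg, "initial_rate must be a single positive number")
  if (length(object@total_epochs) != 1L || object@total_epochs < 1L)
    msg <- c(msg, "total_epochs must be a positive integer")
  if (length(object@num_cycles) != 1L || object@num_cycles < 1L)
    msg <- c(msg, "num_cycles must be a positive integer")
  if (length(msg) == 0L && object@total_epochs %% object@num_cycles != 0L)
    msg <- c(msg, sprintf(
      "total_epochs (%d) must be divisible by num_cycles (%d): uneven cycles are not supported",
      object@total_epochs, object@num_cycles))
  if (length(msg)) msg else TRUE
})

#' Training configuration for the snapshot CNN
#'
#' @slot backbone_id character, one of `"tiny_cnn"` (a small trainable
#'   two-convolution backbone for desk-scale work) or `"mobilenet_v2"`
#'   (the full MobileNetV2 trunk topology, forward pass only, frozen).
#' @slot fc1_units,fc2_units widths of the two custom fully connected layers
#'   appended after the flattened trunk output; `fc2_units` is the
#'   per-snapshot deep-feature dimension tapped for fusion.
#' @slot num_classes number of output classes (softmax width).
#' @slot image_size input spatial size in pixels (images are resized to
#'   `image_size` x `image_size` with bilinear interpolation).
#' @slot channels number of input channels.
#' @slot batch_size mini-batch size for SGD.
#' @slot momentum SGD momentum coefficient in `[0, 1)`.
#' @slot leaky_slope negative slope of the leaky-rectifier activations.
#' @slot freeze_trunk logical; when `TRUE` only the fully connected head is
#'   trained. Forced `TRUE` for the `"mobilenet_v2"` backbone.
#' @slot seed integer seed governing weight initialisation and batch order.
#' @slot schedule a [ScheduleConfig-class] object.
#' @export
setClass("TrainConfig",
  representation(
    backbone_id = "character",
    fc1_units   = "integer",
    fc2_units   = "integer",
    num_classes = "integer",
    image_size  = "integer",
    channels    = "integer",
    batch_size  = "integer",
    momentum    = "numeric",
    leaky_slope = "numeric",
    freeze_trunk = "logical",
    seed        = "integer",
    schedule    = "ScheduleConfig"
  )
)

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (!object@backbone_id %in% c("tiny_cnn", "mobilenet_v2"))
    msg <- c(msg, sprintf("unknown backbone_id '%s'", object@backbone_id))
  if (object@fc2_units < 1L) msg <- c(msg, "fc2_units must be >= 1")
  if (object@fc1_units < 1L) msg <- c(msg, "fc1_units must be >= 1")
  if (object@num_classes < 2L) msg <- c(msg, "num_classes must be >= 2")
  if (object@momentum < 0 || object@momentum >= 1)
    msg <- c(msg, "momentum must be in [0, 1)")
  if (object@batch_size < 1L) msg <- c(msg, "batch_size must be >= 1")
  if (object@image_size < 8L) msg <- c(msg, "image_size must be >= 8")
  if (length(msg)) msg else TRUE
})

#' A convolutional classifier: backbone trunk plus custom head
#'
#' The head is always `flatten -> FC-1 (leaky ReLU) -> FC-2 (leaky ReLU) ->
#' FC classification (softmax)`. Deep features are tapped at the FC-2
#' output (post-activation).
#'
#' @slot config the [TrainConfig-class] the model was built with.
#' @slot trunk list of trunk layer parameter records.
#' @slot head list with dense weights/biases `W1, b1, W2, b2, W3, b3`.
#' @slot flatten_width integer, width of the flattened trunk output.
#' @slot snapshot_index integer; 0 for a live model, the cycle number for a
#'   checkpoint taken at a cycle end.
#' @export
setClass("CNNModel",
  representation(
    config = "TrainConfig",
    trunk = "list",
    head = "list",
    flatten_width = "integer",
    snapshot_index = "integer"
  )
)

#' Checkpoints of one training run
#'
#' One checkpoint is saved at the final epoch of each learning-rate cycle;
#' the checkpoints are the ensemble members used for feature extraction.
#'
#' @slot checkpoints list of [CNNModel-class] snapshots in cycle order.
#' @slot val_accuracy numeric, held-out accuracy of each snapshot.
#' @slot training_log data.frame with one row per epoch: `epoch`,
#'   `learning_rate`, `train_loss`, `val_loss`, `train_acc`, `val_acc`.
#' @slot config the [TrainConfig-class] used.
#' @export
setClass("SnapshotSet",
  representation(
    checkpoints = "list",
    val_accuracy = "numeric",
    training_log = "data.frame",
    config = "TrainConfig"
  )
)

setValidity("SnapshotSet", function(object) {
  msg <- character()
  C <- object@config@schedule@num_cycles
  if (length(object@checkpoints) != C)
    msg <- c(msg, "number of checkpoints must equal num_cycles")
  if (length(object@val_accuracy) != length(object@checkpoints))
    msg <- c(msg, "val_accuracy must have one entry per checkpoint")
  if (length(msg)) msg else TRUE
})

#' Deep-feature matrix with labels, split tag and snapshot provenance
#'
#' Extends \linkS4class{SummarizedExperiment}: the `"features"` assay is
#' stored features x samples (Bioconductor orientation), `colData` carries
#' the integer class label (1-based) and sample identifier of each sample,
#' `rowData` records the snapshot block each feature column originated from,
#' and the split tag (`train`/`val`/`test`) lives in `metadata`. User-facing
#' accessors present the conventional samples x features orientation.
#'
#' @seealso [FeatureMatrix()], [featureValues()], [fuseFeatures()]
#' @export
setClass("FeatureMatrix", contains = "SummarizedExperiment")

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    return("assay 'features' missing")
  v <- SummarizedExperiment::assay(object, "features")
  if (!all(is.finite(v))) msg <- c(msg, "feature values must all be finite")
  cd <- SummarizedExperiment::colData(object)
  if (!"label" %in% colnames(cd)) msg <- c(msg, "colData must contain 'label'")
  rd <- SummarizedExperiment::rowData(object)
  if (!"snapshot_block" %in% colnames(rd))
    msg <- c(msg, "rowData must contain 'snapshot_block'")
  tag <- S4Vectors::metadata(object)$split_tag
  if (is.null(tag) || !tag %in% c("train", "val", "test"))
    msg <- c(msg, "metadata split_tag must be one of train/val/test")
  if (length(msg)) msg else TRUE
})

#' Swarm parameters for binary PSO
#'
#' Defaults follow the published configuration: acceleration constants
#' \eqn{C_1 = C_2 = 1}, 50 iterations, 10 independent repetitions. The
#' population size is not stated in the source configuration and defaults
#' to 20.
#'
#' @slot pop_size number of particles.
#' @slot max_iters maximum iterations \eqn{T} per run.
#' @slot c1,c2 cognitive and social acceleration constants.
#' @slot seed base seed; run `r` uses `seed + r - 1`.
#' @slot n_runs independent repetitions; the best run's result is reported
#'   and per-run metrics are retained for averaging.
#' @slot velocity_clamp velocities are clamped to this magnitude.
#' @slot per_dimension_r logical; `FALSE` (default) draws scalar
#'   \eqn{r_1, r_2} per particle per iteration, `TRUE` draws them per
#'   dimension.
#' @export
setClass("SwarmConfig",
  representation(
    pop_size = "integer", max_iters = "integer",
    c1 = "numeric", c2 = "numeric",
    seed = "integer", n_runs = "integer",
    velocity_clamp = "numeric", per_dimension_r = "logical"
  )
)

setValidity("SwarmConfig", function(object) {
  msg <- character()
  if (object@pop_size < 2L) msg <- c(msg, "pop_size must be >= 2")
  if (object@max_iters < 1L) msg <- c(msg, "max_iters must be >= 1")
  if (object@c1 < 0 || object@c2 < 0) msg <- c(msg, "c1 and c2 must be >= 0")
  if (object@n_runs < 1L) msg <- c(msg, "n_runs must be >= 1")
  if (object@velocity_clamp <= 0) msg <- c(msg, "velocity_clamp must be > 0")
  if (length(msg)) msg else TRUE
})

#' Fitness weighting for wrapper feature selection
#'
#' The fitness of a candidate mask is
#' \eqn{F = \omega \eta + (1 - \omega) \Delta}, where \eqn{\eta} is the
#' accuracy of a k-nearest-neighbour classifier restricted to the selected
#' columns and \eqn{\Delta = (|D| - |d|)/|D|} rewards discarding features.
#'
#' @slot omega weight on accuracy, default 0.99.
#' @slot k_neighbors KNN neighbour count, default 6.
#' @slot full_dim total feature dimension \eqn{|D|}.
#' @export
setClass("FitnessConfig",
  representation(omega = "numeric", k_neighbors = "integer",
                 full_dim = "integer")
)

setValidity("FitnessConfig", function(object) {
  msg <- character()
  if (object@omega < 0 || object@omega > 1) msg <- c(msg, "omega must be in [0, 1]")
  if (object@k_neighbors < 1L) msg <- c(msg, "k_neighbors must be >= 1")
  if (object@full_dim < 1L) msg <- c(msg, "full_dim must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Result of a feature-selection optimisation
#'
#' @slot mask integer 0/1 vector over the full feature dimension.
#' @slot fitness fitness of `mask`.
#' @slot n_selected number of selected features (popcount of `mask`).
#' @slot gbest_history per-iteration global-best fitness of the winning run
#'   (index 1 is the iteration-0 evaluation of the initial swarm).
#' @slot run_seed seed of the winning run.
#' @slot runs list of per-run records (mask, fitness, n_selected, history,
#'   seed) for averaging across repetitions.
#' @export
setClass("FSResult",
  representation(
    mask = "integer", fitness = "numeric", n_selected = "integer",
    gbest_history = "numeric", run_seed = "integer", runs = "list"
  )
)

setValidity("FSResult", function(object) {
  msg <- character()
  if (!all(object@mask %in% c(0L, 1L))) msg <- c(msg, "mask entries must be 0/1")
  if (object@n_selected != sum(object@mask))
    msg <- c(msg, "n_selected must equal popcount(mask)")
  if (is.unsorted(object@gbest_history))
    msg <- c(msg, "gbest_history must be non-decreasing")
  if (length(msg)) msg else TRUE
})

#' Multi-class confusion matrix
#'
#' Orientation is explicit: rows are the predicted class and columns the
#' true class.
#'
#' @slot counts N x N nonnegative integer matrix.
#' @slot orientation fixed string `"rows=predicted,cols=true"`.
#' @export
setClass("ConfusionMatrix",
  representation(counts = "matrix", orientation = "character")
)

setValidity("ConfusionMatrix", function(object) {
  msg <- character()
  if (nrow(object@counts) != ncol(object@counts))
    msg <- c(msg, "counts must be square")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be nonnegative")
  if (any(object@counts != round(object@counts)))
    msg <- c(msg, "counts must be integers")
  if (length(msg)) msg else TRUE
})

#' Classification evaluation report
#'
#' @slot accuracy overall accuracy, `trace(M)/sum(M)`.
#' @slot per_class data.frame with `class`, `precision`, `recall`, `f1`.
#' @slot macro named numeric: unweighted class means of precision, recall, f1.
#' @slot confusion the underlying [ConfusionMatrix-class].
#' @export
setClass("EvalReport",
  representation(
    accuracy = "numeric", per_class = "data.frame",
    macro = "numeric", confusion = "ConfusionMatrix"
  )
)

#' Gradient-weighted class-activation map
#'
#' @slot heat matrix in `[0, 1]`, same spatial size as the input image.
#' @slot class_index class the map explains (1-based).
#' @slot snapshot_index snapshot the checkpoint came from (0 if live model).
#' @export
setClass("ActivationMap",
  representation(heat = "matrix", class_index = "integer",
                 snapshot_index = "integer")
)

setValidity("ActivationMap", function(object) {
  h <- object@heat
  if (!all(is.finite(h))) return("heat values must be finite")
  if (any(h < 0 | h > 1)) return("heat values must lie in [0, 1]")
  TRUE
})

#' Specification of a procedural multi-class texture image set
#'
#' Each class is a sinusoidal grating (class-specific spatial frequency and
#' orientation) superimposed with a Poisson blob field (class-specific
#' density) plus Gaussian pixel noise. The class-discriminative grating can
#' be restricted to a recorded quadrant so that localisation methods can be
#' tested against known ground truth.
#'
#' @slot num_classes,per_class class count and images per class.
#' @slot image_size image side in pixels.
#' @slot channels output channels (the texture is grayscale, replicated).
#' @slot frequencies,orientations,blob_density per-class texture parameters;
#'   parameter tuples must be pairwise distinct.
#' @slot noise_sd Gaussian pixel-noise standard deviation.
#' @slot region `"full"` or one of `"q1".."q4"` (quadrant carrying the
#'   grating, counter-clockwise from top-left).
#' @slot seed integer seed; identical spec + seed gives pixel-identical data.
#' @export
setClass("TextureSpec",
  representation(
    num_classes = "integer", per_class = "integer", image_size = "integer",
    channels = "integer", frequencies = "numeric", orientations = "numeric",
    blob_density = "numeric", noise_sd = "numeric", region = "character",
    seed = "integer"
  )
)

setValidity("TextureSpec", function(object) {
  msg <- character()
  k <- object@num_classes
  if (k < 2L) msg <- c(msg, "num_classes must be >= 2")
  if (object@per_class < 1L) msg <- c(msg, "per_class must be >= 1")
  if (length(object@frequencies) != k || length(object@orientations) != k ||
      length(object@blob_density) != k)
    msg <- c(msg, "per-class parameter vectors must have length num_classes")
  else {
    tup <- paste(object@frequencies, object@orientations, object@blob_density)
    if (anyDuplicated(tup))
      msg <- c(msg, "class parameter tuples must be pairwise distinct")
  }
  if (!object@region %in% c("full", "q1", "q2", "q3", "q4"))
    msg <- c(msg, "region must be 'full' or 'q1'..'q4'")
  if (length(msg)) msg else TRUE
})

#' Specification of a planted-structure feature matrix
#'
#' Emulates fused snapshot deep features: a few informative columns whose
#' class means are separated, noisy copies of informative columns (the
#' cross-snapshot redundancy selection should prune), and class-independent
#' noise columns.
#'
#' @slot num_classes,samples_per_class balanced class layout.
#' @slot n_informative,n_redundant,n_noise column-block sizes; total width is
#'   their sum and the ground-truth informative mask is recorded.
#' @slot class_separation Euclidean distance between closest class means in
#'   the informative subspace.
#' @slot noise_sd within-class (and copy-noise) standard deviation.
#' @slot split_frac named numeric, fractions for train/val/test.
#' @slot seed integer seed.
#' @export
setClass("PlantedFeatureSpec",
  representation(
    num_classes = "integer", samples_per_class = "integer",
    n_informative = "integer", n_redundant = "integer", n_noise = "integer",
    class_separation = "numeric", noise_sd = "numeric",
    split_frac = "numeric", seed = "integer"
  )
)

setValidity("PlantedFeatureSpec", function(object) {
  msg <- character()
  if (object@num_classes < 2L) msg <- c(msg, "num_classes must be >= 2")
  if (object@n_informative < 1L)
    msg <- c(msg, "at least one informative column is required")
  if (object@n_redundant < 0L || object@n_noise < 0L)
    msg <- c(msg, "column counts must be nonnegative")
  if (object@noise_sd < 0) msg <- c(msg, "noise_sd must be >= 0")
  sf <- object@split_frac
  if (length(sf) != 3L || !setequal(names(sf), c("train", "val", "test")) ||
      abs(sum(sf) - 1) > 1e-8 || any(sf <= 0))
    msg <- c(msg, "split_frac must be positive fractions named train/val/test summing to 1")
  if (length(msg)) msg else TRUE
})
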