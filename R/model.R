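#' Create a training configuration
#'
#' Defaults mirror the reference setup: 4096- and 256-unit fully connected
#' layers with leaky-ReLU activations appended after the flattened trunk,
#' softmax classification layer, SGD with momentum 0.9, batch size 32,
#' bilinear resize to 224 x 224. The loss is categorical cross-entropy on
#' the softmax outputs. Batch size, momentum and the leaky slope are
#' engineering defaults surfaced here rather than hard-coded.
#'
#' @param backbone_id `"tiny_cnn"` (trainable desk-scale backbone) or
#'   `"mobilenet_v2"` (full-size trunk, forward-only, frozen).
#' @param num_classes number of classes (>= 2).
#' @param fc1_units,fc2_units widths of the custom head layers; `fc2_units`
#'   is the deep-feature dimension tapped per snapshot.
#' @param image_size,channels input geometry.
#' @param batch_size,momentum,leaky_slope SGD and activation parameters.
#' @param freeze_trunk train only the head when `TRUE`. The
#'   `"mobilenet_v2"` trunk has no backward pass and is always frozen.
#' @param seed integer seed for weight initialisation and batch order.
#' @param schedule a [ScheduleConfig-class]; default is the reference
#'   schedule (`2e-4`, 100 epochs, 5 cycles).
#' @return a [TrainConfig-class] object.
#' @export
trainConfig <- function(backbone_id = "mobilenet_v2", num_classes = 8L,
                        fc1_units = 4096L, fc2_units = 256L,
                        image_size = 224L, channels = 3L,
                        batch_size = 32L, momentum = 0.9,
                        leaky_slope = 0.01, freeze_trunk = NULL,
                        seed = 1L, schedule = scheduleConfig()) {
  if (is.null(freeze_trunk)) freeze_trunk <- backbone_id == "mobilenet_v2"
  if (backbone_id == "mobilenet_v2" && !freeze_trunk) {
    warning("the mobilenet_v2 trunk is forward-only; forcing freeze_trunk = TRUE")
    freeze_trunk <- TRUE
  }
  new("TrainConfig", backbone_id = backbone_id,
      fc1_units = as.integer(fc1_units), fc2_units = as.integer(fc2_units),
      num_classes = as.integer(num_classes),
      image_size = as.integer(image_size), channels = as.integer(channels),
      batch_size = as.integer(batch_size), momentum = as.numeric(momentum),
      leaky_slope = as.numeric(leaky_slope),
      freeze_trunk = isTRUE(freeze_trunk), seed = as.integer(seed),
      schedule = schedule)
}

#' Build the backbone-plus-head classifier
#'
#' Constructs `trunk -> flatten -> FC-1 (leaky ReLU) -> FC-2 (leaky ReLU) ->
#' FC classification (softmax)`. All weights (trunk included) are
#' initialised from `config@seed` with He-scaled Gaussians, so two builds
#' from the same configuration are identical. With the default
#' `"mobilenet_v2"` backbone at 224 x 224 input the flattened trunk output
#' has 62720 units (7 x 7 x 1280).
#'
#' @param config a [TrainConfig-class].
#' @return a [CNNModel-class].
#' @export
buildModel <- function(config) {
  validObject(config)
  set.seed(config@seed)
  if (config@backbone_id == "tiny_cnn") {
    trunk <- .build_tiny_trunk(config@channels)
    fw <- .tiny_flatten_width(config@image_size)
  } else {
    trunk <- .build_mobilenet_trunk(config@channels)
    fw <- .mbv2_flatten_width(config@image_size)
  }
  head <- list(
    W1 = .he_weights(fw, config@fc1_units, fw), b1 = numeric(config@fc1_units),
    W2 = .he_weights(config@fc1_units, config@fc2_units, config@fc1_units),
    b2 = numeric(config@fc2_units),
    W3 = .he_weights(config@fc2_units, config@num_classes, config@fc2_units),
    b3 = numeric(config@num_classes))
  new("CNNModel", config = config, trunk = trunk, head = head,
      flatten_width = as.integer(fw), snapshot_index = 0L)
}

# Head forward from flattened features; returns logits, probabilities and
# the FC-2 post-activation tap. Caches activations for backprop on demand.
.head_forward <- function(head, flat, slope, cache = FALSE) {
  z1 <- .dense_forward(flat, head$W1, head$b1)
  a1 <- .leaky_forward(z1, slope)
  z2 <- .dense_forward(a1$out, head$W2, head$b2)
  a2 <- .leaky_forward(z2, slope)
  z3 <- .dense_forward(a2$out, head$W3, head$b3)
  out <- list(logits = z3, probs = .softmax(z3), features = a2$out)
  if (cache)
    out$cache <- list(flat = flat, a1 = a1$out, neg1 = a1$cache,
                      a2 = a2$out, neg2 = a2$cache)
  out
}

# Backprop through the head given dz (gradient at the logits). Returns
# parameter gradients and the gradient at the flattened trunk output.
.head_backward <- function(head, cache, dz, slope) {
  dW3 <- crossprod(cache$a2, dz); db3 <- colSums(dz)
  da2 <- .leaky_backward(dz %*% t(head$W3), cache$neg2, slope)
  dW2 <- crossprod(cache$a1, da2); db2 <- colSums(da2)
  da1 <- .leaky_backward(da2 %*% t(head$W2), cache$neg1, slope)
  dW1 <- crossprod(cache$flat, da1); db1 <- colSums(da1)
  list(dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2, dW3 = dW3, db3 = db3,
       dflat = da1 %*% t(head$W1))
}

# Inputs arrive in [0, 1]; centre and rescale to [-1, 1] (the channel
# statistics convention of the reference trunk's pretraining pipeline).
.normalize_input <- function(x) (x - 0.5) * 2

# Full forward pass: x (H, W, C, N) -> probs, features, flat.
.model_forward <- function(model, x, cache = FALSE) {
  x <- .normalize_input(x)
  cfg <- model@config
  if (cfg@backbone_id == "tiny_cnn") {
    tf <- .tiny_forward(model@trunk, x, cfg@leaky_slope, cache = cache)
  } else {
    tf <- .mbv2_forward(model@trunk, x)
  }
  hf <- .head_forward(model@head, tf$flat, cfg@leaky_slope, cache = cache)
  list(trunk = tf, head = hf, probs = hf$probs, features = hf$features)
}

#' Class probabilities for a batch of images
#'
#' @param model a [CNNModel-class].
#' @param x image array `(H, W, C, N)` (a single `(H, W, C)` image is
#'   accepted and treated as a batch of one).
#' @return an `N x num_classes` matrix of softmax probabilities.
#' @export
predictProba <- function(model, x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  .model_forward(model, x)$probs
}

.check_dataset <- function(x, y, num_classes, what = "training") {
  if (length(dim(x)) != 4L) stop("images must be an (H, W, C, N) array")
  n <- dim(x)[4]
  if (n == 0L || length(y) == 0L) stop(sprintf("%s split is empty", what))
  if (length(y) != n) stop("label length must match image count")
  if (!all(y %in% seq_len(num_classes)))
    stop("labels must be integers in 1..num_classes")
  missing <- setdiff(seq_len(num_classes), unique(y))
  if (what == "training" && length(missing))
    stop(sprintf("class(es) %s absent from the training split",
                 paste(missing, collapse = ", ")))
  invisible(n)
}

.eval_split <- function(model, x, y, batch = 64L) {
  n <- dim(x)[4]
  losses <- numeric(0); correct <- 0L
  for (start in seq(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    fw <- .model_forward(model, x[, , , idx, drop = FALSE])
    sc <- .softmax_xent(fw$head$logits, y[idx])
    losses <- c(losses, sc$loss * length(idx))
    correct <- correct + sum(max.col(sc$probs, ties.method = "first") == y[idx])
  }
  list(loss = sum(losses) / n, acc = correct / n)
}

#' Train one network, checkpointing a snapshot at each cycle end
#'
#' Runs SGD with momentum under the cyclic cosine-annealing schedule held in
#' `model@config@schedule`; the learning rate is updated once per epoch. The
#' model state after the final epoch of each cycle is saved as a snapshot,
#' together with its validation accuracy, giving `num_cycles` ensemble
#' members from a single training run. With `freeze_trunk = TRUE` the trunk
#' activations are computed once and only the fully connected head is
#' optimised.
#'
#' Two runs with identical configuration (seed included) and inputs produce
#' bitwise-identical training logs and checkpoints.
#'
#' @param model a [CNNModel-class] from [buildModel()].
#' @param x,y training images `(H, W, C, N)` and 1-based integer labels;
#'   every class must be present.
#' @param x_val,y_val held-out split used for the per-snapshot accuracy.
#' @return a [SnapshotSet-class].
#' @export
trainSnapshots <- function(model, x, y, x_val, y_val) {
  cfg <- model@config
  sched <- cfg@schedule
  validObject(sched)
  y <- as.integer(y); y_val <- as.integer(y_val)
  n <- .check_dataset(x, y, cfg@num_classes, "training")
  .check_dataset(x_val, y_val, cfg@num_classes, "validation")

  frozen <- cfg@freeze_trunk
  slope <- cfg@leaky_slope
  if (frozen) {
    flat_train <- .model_forward(model, x)$trunk$flat
    flat_val <- .model_forward(model, x_val)$trunk$flat
  }

  vel <- list(W1 = 0, b1 = 0, W2 = 0, b2 = 0, W3 = 0, b3 = 0)
  trunk_vel <- lapply(model@trunk, function(l)
    if (!is.null(l$W)) list(W = 0, b = 0) else NULL)

  snaps <- snapshotEpochs(sched)
  checkpoints <- list(); val_accs <- numeric(0)
  log <- data.frame()
  set.seed(cfg@seed + 1L)  # batch-order stream, separate from init
  for (epoch in seq_len(sched@total_epochs)) {
    lr <- learningRate(sched, epoch)
    order_idx <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0L
    for (start in seq(1L, n, by = cfg@batch_size)) {
      idx <- order_idx[start:min(start + cfg@batch_size - 1L, n)]
      yb <- y[idx]
      if (frozen) {
        flat <- flat_train[idx, , drop = FALSE]
        hf <- .head_forward(model@head, flat, slope, cache = TRUE)
        sc <- .softmax_xent(hf$logits, yb)
        hb <- .head_backward(model@head, hf$cache, sc$dz, slope)
      } else {
        fw <- .model_forward(model, x[, , , idx, drop = FALSE], cache = TRUE)
        sc <- .softmax_xent(fw$head$logits, yb)
        hb <- .head_backward(model@head, fw$head$cache, sc$dz, slope)
        tb <- .tiny_backward(model@trunk, fw$trunk, hb$dflat, slope)
        for (li in seq_along(model@trunk)) {
          g <- tb$grads[[li]]
          if (is.null(g)) next
          up <- .sgd_step(model@trunk[[li]]$W, g$dW, trunk_vel[[li]]$W,
                          lr, cfg@momentum)
          model@trunk[[li]]$W <- up$param; trunk_vel[[li]]$W <- up$vel
          up <- .sgd_step(model@trunk[[li]]$b, g$db, trunk_vel[[li]]$b,
                          lr, cfg@momentum)
          model@trunk[[li]]$b <- up$param; trunk_vel[[li]]$b <- up$vel
        }
      }
      if (!is.finite(sc$loss))
        stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch))
      for (pn in c("W1", "b1", "W2", "b2", "W3", "b3")) {
        up <- .sgd_step(model@head[[pn]], hb[[paste0("d", pn)]], vel[[pn]],
                        lr, cfg@momentum)
        model@head[[pn]] <- up$param; vel[[pn]] <- up$vel
      }
      ep_loss <- ep_loss + sc$loss * length(idx)
      ep_correct <- ep_correct +
        sum(max.col(sc$probs, ties.method = "first") == yb)
    }
    if (frozen) {
      hv <- .head_forward(model@head, flat_val, slope)
      scv <- .softmax_xent(hv$logits, y_val)
      val <- list(loss = scv$loss,
                  acc = mean(max.col(scv$probs, ties.method = "first") == y_val))
    } else {
      val <- .eval_split(model, x_val, y_val)
    }
    log <- rbind(log, data.frame(
      epoch = epoch, learning_rate = lr, train_loss = ep_loss / n,
      val_loss = val$loss, train_acc = ep_correct / n, val_acc = val$acc))
    if (epoch %in% snaps) {
      snap <- model
      snap@snapshot_index <- match(epoch, snaps)
      checkpoints[[length(checkpoints) + 1L]] <- snap
      val_accs <- c(val_accs, val$acc)
    }
  }
  new("SnapshotSet", checkpoints = checkpoints, val_accuracy = val_accs,
      training_log = log, config = cfg)
}

#' @rdname SnapshotSet-accessors
#' @param x a [SnapshotSet-class].
#' @export
setMethod("checkpoints", "SnapshotSet", function(x) x@checkpoints)

#' Accessors for snapshot training runs
#'
#' `checkpoints()` returns the list of snapshot models in cycle order,
#' `valAccuracy()` their held-out accuracies, and `trainingLog()` the
#' per-epoch data.frame (`epoch`, `learning_rate`, `train_loss`,
#' `val_loss`, `train_acc`, `val_acc`).
#'
#' @rdname SnapshotSet-accessors
#' @export
setMethod("valAccuracy", "SnapshotSet", function(x) x@val_accuracy)

#' @rdname SnapshotSet-accessors
#' @export
setMethod("trainingLog", "SnapshotSet", function(x) x@training_log)

setMethod("show", "CNNModel", function(object) {
  cfg <- object@config
  cat(sprintf("CNNModel (%s): %dx%dx%d input -> flatten %d -> FC %d -> FC %d -> %d classes\n",
              cfg@backbone_id, cfg@image_size, cfg@image_size, cfg@channels,
              object@flatten_width, cfg@fc1_units, cfg@fc2_units,
              cfg@num_classes))
  if (object@snapshot_index > 0L)
    cat(sprintf("snapshot #%d\n", object@snapshot_index))
})

setMethod("show", "SnapshotSet", function(object) {
  cat(sprintf("SnapshotSet: %d snapshots over %d epochs (%s backbone)\n",
              length(object@checkpoints), object@config@schedule@total_epochs,
              object@config@backbone_id))
  cat("val accuracy:", paste(sprintf("%.3f", object@val_accuracy),
                             collapse = ", "), "\n")
})
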