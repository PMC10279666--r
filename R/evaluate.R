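#' Build a confusion matrix from predictions
#'
#' Orientation is rows = predicted class, columns = true class; entry
#' `M[p, t]` counts samples predicted `p` whose true class is `t`.
#'
#' @param pred,truth equal-length 1-based integer label vectors.
#' @param n_classes number of classes `N`; defaults to the largest label
#'   seen.
#' @return a [ConfusionMatrix-class].
#' @examples
#' confusionMatrix(c(1, 1, 2, 2), c(1, 2, 1, 2))
#' @export
confusionMatrix <- function(pred, truth, n_classes = max(pred, truth, 1L)) {
  pred <- as.integer(pred); truth <- as.integer(truth)
  if (length(pred) != length(truth))
    stop("pred and truth must have equal length")
  if (length(pred) &&
      (any(pred < 1L | pred > n_classes) || any(truth < 1L | truth > n_classes)))
    stop("labels out of range 1..n_classes")
  counts <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(pred))
    counts[pred[i], truth[i]] <- counts[pred[i], truth[i]] + 1L
  dimnames(counts) <- list(predicted = seq_len(n_classes),
                           true = seq_len(n_classes))
  new("ConfusionMatrix", counts = counts,
      orientation = "rows=predicted,cols=true")
}

#' @rdname EvalReport-accessors
#' @export
setMethod("confusionCounts", "ConfusionMatrix", function(x) x@counts)

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (rows = predicted, cols = true):\n")
  print(object@counts)
})

#' Confusion-matrix classification metrics
#'
#' Accuracy is `trace(M) / sum(M)`. Per-class precision divides the
#' diagonal entry by the predicted-class total (row sum under this
#' orientation) and recall by the true-class total (column sum); F1 is
#' their harmonic mean. Headline values are macro averages (unweighted
#' class means) — on class-balanced data these coincide with weighted
#' averages. A class with a zero denominator scores 0 for that metric,
#' with a warning.
#'
#' @param cm a [ConfusionMatrix-class] (or a square counts matrix, taken
#'   as rows = predicted).
#' @return an [EvalReport-class].
#' @examples
#' r <- evalMetrics(matrix(c(40, 10, 10, 40), 2))
#' accuracyOf(r)       # 0.8
#' @export
evalMetrics <- function(cm) {
  if (!is(cm, "ConfusionMatrix")) {
    cm <- new("ConfusionMatrix", counts = as.matrix(cm),
              orientation = "rows=predicted,cols=true")
  }
  M <- cm@counts
  total <- sum(M)
  if (total == 0) stop("empty confusion matrix")
  N <- nrow(M)
  diagM <- diag(M)
  pred_tot <- rowSums(M)   # predicted-class totals
  true_tot <- colSums(M)   # true-class totals
  if (any(pred_tot == 0) || any(true_tot == 0))
    warning("class(es) with zero predicted or true totals score 0")
  precision <- ifelse(pred_tot > 0, diagM / pred_tot, 0)
  recall <- ifelse(true_tot > 0, diagM / true_tot, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  new("EvalReport",
      accuracy = sum(diagM) / total,
      per_class = data.frame(class = seq_len(N), precision = precision,
                             recall = recall, f1 = f1, row.names = NULL),
      macro = c(precision = mean(precision), recall = mean(recall),
                f1 = mean(f1)),
      confusion = cm)
}

#' Accessors for evaluation reports
#'
#' `accuracyOf()` the overall accuracy, `macroMetrics()` the named macro
#' precision/recall/F1 vector, `perClassMetrics()` the per-class
#' data.frame, `confusionCounts()` the raw counts matrix.
#'
#' @param x an [EvalReport-class] (or [ConfusionMatrix-class] for
#'   `confusionCounts`).
#' @rdname EvalReport-accessors
#' @export
setMethod("accuracyOf", "EvalReport", function(x) x@accuracy)

#' @rdname EvalReport-accessors
#' @export
setMethod("macroMetrics", "EvalReport", function(x) x@macro)

#' @rdname EvalReport-accessors
#' @export
setMethod("perClassMetrics", "EvalReport", function(x) x@per_class)

#' @rdname EvalReport-accessors
#' @export
setMethod("confusionCounts", "EvalReport", function(x) x@confusion@counts)

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: accuracy %.4f | macro P %.4f R %.4f F1 %.4f (%d classes)\n",
              object@accuracy, object@macro["precision"],
              object@macro["recall"], object@macro["f1"],
              nrow(object@per_class)))
})

#' Write an evaluation report as JSON
#'
#' Metrics are rounded to 4 decimals; the confusion matrix is written as
#' nested integer lists.
#'
#' @param report an [EvalReport-class].
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeEvalReport <- function(report, file) {
  jsonlite::write_json(list(
    accuracy = round(report@accuracy, 4),
    macro = as.list(round(report@macro, 4)),
    per_class = lapply(seq_len(nrow(report@per_class)), function(i)
      lapply(report@per_class[i, ], function(v)
        if (is.numeric(v)) round(v, 4) else v)),
    confusion = apply(report@confusion@counts, 1L, as.integer,
                      simplify = FALSE)),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Stratified fold assignment
#'
#' Shuffles each class independently with a seeded RNG and deals its
#' samples round-robin over `folds`, so every fold holds (as near as
#' possible) `1/folds` of every class. Folds are pairwise disjoint and
#' cover all samples.
#'
#' @param labels integer class labels.
#' @param folds number of folds, >= 2; every class must have at least
#'   `folds` members.
#' @param seed RNG seed for the per-class shuffles.
#' @return integer vector of fold assignments in `1..folds`.
#' @export
stratifiedFolds <- function(labels, folds = 5L, seed = 1L) {
  folds <- as.integer(folds)
  if (folds < 2L)
    stop("folds must be >= 2 (a single fold leaves no held-out data)")
  labels <- as.integer(labels)
  tab <- table(labels)
  if (any(tab < folds))
    stop("every class needs at least `folds` samples")
  set.seed(seed)
  assign <- integer(length(labels))
  for (cl in as.integer(names(tab))) {
    idx <- sample(which(labels == cl))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Stratified k-fold cross-validated KNN evaluation
#'
#' Splits the samples of a [FeatureMatrix-class] into stratified folds,
#' and for each fold trains the KNN on the remaining folds and scores the
#' held-out one. Optionally a binary-PSO selection step runs inside each
#' training fold (on an inner stratified train/val split of the training
#' portion, so the scored fold never influences selection).
#'
#' @param fm a [FeatureMatrix-class] with all samples.
#' @param k KNN neighbour count.
#' @param folds number of folds (default 5).
#' @param seed seed for fold assignment (recorded in the result).
#' @param swarm,fit optional [SwarmConfig-class] / [FitnessConfig-class];
#'   when both are given, feature selection is performed per fold.
#' @return list with `reports` (per-fold [EvalReport-class]), `summary`
#'   (data.frame of mean and sd per metric), `fold_assign` and `seed`.
#' @export
crossValidate <- function(fm, k = 6L, folds = 5L, seed = 1L,
                          swarm = NULL, fit = NULL) {
  labels <- sampleLabels(fm)
  assign <- stratifiedFolds(labels, folds, seed)
  vals <- featureValues(fm)
  reports <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- which(assign != f); te <- which(assign == f)
    Xtr <- vals[tr, , drop = FALSE]; ytr <- labels[tr]
    Xte <- vals[te, , drop = FALSE]; yte <- labels[te]
    if (!is.null(swarm) && !is.null(fit)) {
      inner <- stratifiedFolds(ytr, 4L, seed + f)
      inner_tr <- FeatureMatrix(Xtr[inner != 1L, , drop = FALSE],
                                ytr[inner != 1L], "train")
      inner_val <- FeatureMatrix(Xtr[inner == 1L, , drop = FALSE],
                                 ytr[inner == 1L], "val")
      sel <- which(selectionMask(runBPSO(inner_tr, inner_val, swarm, fit)) == 1L)
      Xtr <- Xtr[, sel, drop = FALSE]; Xte <- Xte[, sel, drop = FALSE]
    }
    pred <- .knn_predict_matrix(Xtr, ytr, Xte, k)
    reports[[f]] <- evalMetrics(confusionMatrix(pred, yte,
                                                max(labels)))
  }
  metrics <- data.frame(
    accuracy = vapply(reports, accuracyOf, numeric(1)),
    precision = vapply(reports, function(r) macroMetrics(r)["precision"],
                       numeric(1)),
    recall = vapply(reports, function(r) macroMetrics(r)["recall"], numeric(1)),
    f1 = vapply(reports, function(r) macroMetrics(r)["f1"], numeric(1)))
  summary <- data.frame(metric = names(metrics),
                        mean = vapply(metrics, mean, numeric(1)),
                        sd = vapply(metrics, sd, numeric(1)),
                        row.names = NULL)
  list(reports = reports, summary = summary, fold_assign = assign,
       seed = seed)
}

#' McNemar's paired test between two classifiers
#'
#' Counts the discordant pairs — `b` samples classifier A gets right and B
#' wrong, `c` the reverse — and computes the continuity-corrected
#' chi-square statistic \eqn{(|b - c| - 1)^2 / (b + c)} on 1 degree of
#' freedom. With no discordant pairs the classifiers are indistinguishable
#' and `p = 1`.
#'
#' @param pred_a,pred_b predictions of the two classifiers.
#' @param truth true labels.
#' @return list with `statistic`, `p_value`, `b`, `c`.
#' @examples
#' # b = 15, c = 5 -> statistic (10 - 1)^2 / 20 = 4.05
#' @export
mcnemarTest <- function(pred_a, pred_b, truth) {
  if (length(pred_a) != length(truth) || length(pred_b) != length(truth))
    stop("prediction and truth vectors must have equal length")
  a_right <- pred_a == truth
  b_right <- pred_b == truth
  b <- sum(a_right & !b_right)
  cc <- sum(!a_right & b_right)
  if (b + cc == 0)
    return(list(statistic = 0, p_value = 1, b = b, c = cc))
  stat <- (abs(b - cc) - 1)^2 / (b + cc)
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       b = b, c = cc)
}
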