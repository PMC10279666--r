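# Deterministic Euclidean k-nearest-neighbour core. Tie handling is part of
# the contract (k = 6 is even): a tied majority vote goes to the class of
# the single nearest neighbour among the tied classes, and tied distances
# are broken by the lower training-sample index.

.knn_predict_matrix <- function(Xtr, ytr, Xte, k) {
  ntr <- nrow(Xtr); nte <- nrow(Xte)
  if (k > ntr) stop("k cannot exceed the number of training samples")
  K <- max(ytr)
  d2 <- matrix(rowSums(Xte * Xte), nte, ntr) +
    rep(rowSums(Xtr * Xtr), each = nte) - 2 * tcrossprod(Xte, Xtr)
  pred <- integer(nte)
  for (i in seq_len(nte)) {
    ord <- order(d2[i, ], seq_len(ntr))
    nn_cls <- ytr[ord[seq_len(k)]]
    votes <- tabulate(nn_cls, nbins = K)
    top <- which(votes == max(votes))
    pred[i] <- if (length(top) == 1L) top else nn_cls[nn_cls %in% top][1L]
  }
  pred
}

.knn_accuracy <- function(Xtr, ytr, Xev, yev, k) {
  mean(.knn_predict_matrix(Xtr, ytr, Xev, k) == yev)
}

#' k-nearest-neighbour classification
#'
#' Euclidean-distance majority vote among the `k` closest training samples,
#' with the deterministic tie rules documented above (vote ties fall to the
#' class of the nearest neighbour among the tied classes; distance ties to
#' the lower training index). Deterministic given its inputs.
#'
#' @param train a [FeatureMatrix-class] (or samples x features matrix).
#' @param test a [FeatureMatrix-class] (or matrix) of equal width.
#' @param k neighbour count; must not exceed the training size. Default 6.
#' @param train_labels labels when `train` is a bare matrix.
#' @return integer vector of predicted labels for the test rows.
#' @export
knnClassify <- function(train, test, k = 6L, train_labels = NULL) {
  if (is(train, "FeatureMatrix")) {
    train_labels <- sampleLabels(train)
    Xtr <- featureValues(train)
  } else Xtr <- as.matrix(train)
  Xte <- if (is(test, "FeatureMatrix")) featureValues(test) else as.matrix(test)
  if (ncol(Xtr) != ncol(Xte))
    stop("train and test feature widths differ")
  .knn_predict_matrix(Xtr, as.integer(train_labels), Xte, as.integer(k))
}
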