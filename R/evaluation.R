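#' One-vs-rest confusion counts per class
#'
#' For each class `k`, counts TP (predicted and labelled `k`), FN
#' (labelled `k`, predicted otherwise), FP (predicted `k`, labelled
#' otherwise) and TN (neither). Per class the four counts always sum to the
#' number of evaluated items.
#'
#' @param predictions,labels equal-length 1-based integer vectors.
#' @param num_classes number of classes.
#' @return `num_classes x 4` data frame with columns `TP`, `FN`, `FP`, `TN`.
#' @export
confusion_counts <- function(predictions, labels, num_classes) {
  stopifnot(length(predictions) == length(labels))
  if (any(predictions < 1L | predictions > num_classes) ||
      any(labels < 1L | labels > num_classes))
    stop("labels and predictions must lie in 1..num_classes", call. = FALSE)
  n <- length(labels)
  out <- t(vapply(seq_len(num_classes), function(k) {
    tp <- sum(predictions == k & labels == k)
    fn <- sum(predictions != k & labels == k)
    fp <- sum(predictions == k & labels != k)
    c(TP = tp, FN = fn, FP = fp, TN = n - tp - fn - fp)
  }, numeric(4)))
  as.data.frame(out)
}

#' Confusion-matrix metrics
#'
#' Literal evaluation of the four standard formulas on one set of counts:
#' accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)` and F-score `2TP/(2TP+FP+FN)`. A zero denominator returns
#' 0 for that metric, flagged in the `degenerate` attribute.
#'
#' @param counts named numeric vector or one-row data frame with `TP`,
#'   `TN`, `FP`, `FN`.
#' @return named numeric vector `accuracy`, `sensitivity`, `specificity`,
#'   `f_score`.
#' @export
classification_metrics <- function(counts) {
  counts <- as.list(counts)
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  if (tp + tn + fp + fn == 0)
    stop("all counts are zero", call. = FALSE)
  safe <- function(num, den) if (den == 0) 0 else num / den
  out <- c(accuracy = safe(tp + tn, tp + tn + fp + fn),
           sensitivity = safe(tp, tp + fn),
           specificity = safe(tn, tn + fp),
           f_score = safe(2 * tp, 2 * tp + fp + fn))
  attr(out, "degenerate") <- names(out)[c(FALSE, tp + fn == 0, tn + fp == 0,
                                          2 * tp + fp + fn == 0)]
  out
}

#' Macro one-vs-rest AUC
#'
#' For each class the binary AUC is computed with the Mann-Whitney rank
#' statistic (the probability that a random positive scores above a random
#' negative, counting ties as half), then averaged without weighting
#' across classes. Invariant to any strictly monotone transform of the
#' scores.
#'
#' @param scores `N x K` matrix of per-class scores (e.g. probabilities).
#' @param labels 1-based integer labels of length `N`.
#' @return macro-averaged AUC in `[0, 1]`.
#' @export
macro_auc <- function(scores, labels) {
  stopifnot(is.matrix(scores), nrow(scores) == length(labels))
  if (length(unique(labels)) < 2L)
    stop("AUC is undefined with a single observed class", call. = FALSE)
  classes <- sort(unique(labels))
  aucs <- vapply(classes, function(k) {
    pos <- labels == k
    n1 <- sum(pos); n0 <- sum(!pos)
    r <- rank(scores[, k]) # midranks handle ties
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
  mean(aucs)
}

#' Majority-voting image-level aggregation
#'
#' Each image's label is the mode of its patch predictions; ties are broken
#' by the larger mean class probability over the image's patches (ties on
#' class index never decide the outcome). Deterministic.
#'
#' @param patch_predictions 1-based predicted labels, one per patch.
#' @param image_ids identifier per patch grouping patches into images.
#' @param patch_probabilities optional `N x K` probability matrix; required
#'   only when a vote is tied.
#' @return named integer vector, one label per image id.
#' @export
majority_vote <- function(patch_predictions, image_ids,
                          patch_probabilities = NULL) {
  stopifnot(length(patch_predictions) == length(image_ids))
  ids <- unique(image_ids)
  out <- vapply(ids, function(id) {
    sel <- image_ids == id
    votes <- table(patch_predictions[sel])
    winners <- as.integer(names(votes)[votes == max(votes)])
    if (length(winners) == 1L) return(winners)
    if (is.null(patch_probabilities))
      stop("tie for image ", id, " and no probabilities to break it",
           call. = FALSE)
    mp <- colMeans(patch_probabilities[sel, , drop = FALSE])
    winners[which.max(mp[winners])]
  }, integer(1))
  names(out) <- as.character(ids)
  out
}

#' Full evaluation report for a set of predictions
#'
#' Assembles per-class one-vs-rest counts, per-class and macro-averaged
#' metrics, overall (multi-class) accuracy, macro AUC and the row-normalized
#' confusion matrix.
#'
#' @param predictions,labels 1-based integer vectors.
#' @param scores optional `N x K` score matrix for the AUC.
#' @param num_classes number of classes (inferred if missing).
#' @return a `metric_report` list.
#' @export
metric_report <- function(predictions, labels, scores = NULL,
                          num_classes = max(labels, predictions)) {
  counts <- confusion_counts(predictions, labels, num_classes)
  per_class <- t(apply(counts, 1L, classification_metrics))
  macro <- colMeans(per_class)
  cm <- matrix(0, num_classes, num_classes)
  for (i in seq_along(labels))
    cm[labels[i], predictions[i]] <- cm[labels[i], predictions[i]] + 1
  cm_norm <- cm / pmax(rowSums(cm), 1)
  out <- list(accuracy = mean(predictions == labels),
              per_class = as.data.frame(per_class),
              macro = macro,
              confusion = cm,
              confusion_normalized = cm_norm,
              auc = if (!is.null(scores)) macro_auc(scores, labels))
  structure(out, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("accuracy: %.4f\n", x$accuracy))
  cat(sprintf("macro sensitivity: %.4f  specificity: %.4f  F-score: %.4f\n",
              x$macro["sensitivity"], x$macro["specificity"],
              x$macro["f_score"]))
  if (!is.null(x$auc)) cat(sprintf("macro AUC: %.4f\n", x$auc))
  cat("normalized confusion matrix:\n")
  print(round(x$confusion_normalized, 3))
  invisible(x)
}

#' Evaluate a trained model on a labelled sample set
#'
#' @param model a `danet_model`.
#' @param samples list of samples (`image`, `mask`, `label`).
#' @param batch_size forward batch size.
#' @return a [metric_report()].
#' @export
evaluate_danet <- function(model, samples, batch_size = 32L) {
  labels <- vapply(samples, function(s) as.integer(s$label), integer(1))
  pr <- predict_danet(model, samples, batch_size)
  metric_report(pr$labels, labels, pr$probs, model$config$num_classes)
}
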