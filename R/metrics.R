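# Evaluation metrics. All quantities derive from confusion-matrix counts:
# accuracy = (TP+TN)/(TP+TN+FP+FN), precision = TP/(TP+FP),
# recall = TP/(TP+FN), F1 = 2PR/(P+R), and ROC-AUC from the TPR/FPR sweep
# (TPR = TP/(TP+FN), FPR = FP/(FP+TN)); 1 is perfect separation, 0.5 is
# chance. Multiclass tasks use one-vs-rest counts per class and unweighted
# (macro) averages, with per-class values retained.

# Trapezoidal ROC-AUC for a binary problem from positive-class scores.
.roc_auc_binary <- function(y, score) {
  pos <- y == 1L
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  ord <- order(score, decreasing = TRUE)
  ys <- pos[ord]
  ss <- score[ord]
  tp <- cumsum(ys); fp <- cumsum(!ys)
  # one operating point per distinct threshold
  last <- c(ss[-1] != ss[-length(ss)], TRUE)
  tpr <- c(0, tp[last] / n1)
  fpr <- c(0, fp[last] / n0)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Compute the metric suite from labels and scores
#'
#' Builds the full confusion matrix from argmax predictions, the
#' one-vs-rest counts per class, accuracy, precision, recall, F1 and
#' ROC-AUC. Binary tasks report the positive-class (label 1) precision,
#' recall and F1 and use the positive-class score for the ROC; multiclass
#' tasks report unweighted macro averages (per-class values retained) and
#' macro one-vs-rest ROC-AUC.
#'
#' @param y_true Integer labels in `[0, n_classes)`.
#' @param scores Matrix `[N x n_classes]` of per-class probabilities or
#'   logits (argmax and score ranks are what matter).
#' @param class_names Optional class names.
#' @return An object of class `metrics_report`: a list with `accuracy`,
#'   `precision`, `recall`, `f1`, `roc_auc`, `confusion` (rows = true
#'   class), and `per_class` (data frame with TP/TN/FP/FN and per-class
#'   rates).
#' @export
compute_metrics <- function(y_true, scores, class_names = NULL) {
  y_true <- as.integer(y_true)
  if (is.vector(scores)) scores <- cbind(1 - scores, scores)
  K <- ncol(scores)
  N <- length(y_true)
  stopifnot(nrow(scores) == N, all(y_true >= 0), all(y_true < K))
  if (is.null(class_names)) class_names <- as.character(seq_len(K) - 1L)
  pred <- max.col(scores, ties.method = "first") - 1L
  confusion <- matrix(0L, K, K, dimnames = list(true = class_names,
                                                pred = class_names))
  for (i in seq_len(N))
    confusion[y_true[i] + 1L, pred[i] + 1L] <-
      confusion[y_true[i] + 1L, pred[i] + 1L] + 1L
  tp <- as.integer(unname(diag(confusion)))
  fp <- as.integer(unname(colSums(confusion))) - tp
  fn <- as.integer(unname(rowSums(confusion))) - tp
  tn <- N - tp - fp - fn
  prec_k <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec_k <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1_k <- ifelse(prec_k + rec_k > 0,
                 2 * prec_k * rec_k / (prec_k + rec_k), 0)
  single_class <- length(unique(y_true)) < 2L
  auc_k <- rep(NA_real_, K)
  if (single_class) {
    warning("ROC-AUC undefined: y_true contains a single class",
            call. = FALSE)
  } else {
    for (k in seq_len(K)) {
      yk <- as.integer(y_true == k - 1L)
      if (length(unique(yk)) == 2L)
        auc_k[k] <- .roc_auc_binary(yk, scores[, k])
    }
  }
  if (K == 2L) {
    precision <- prec_k[2]; recall <- rec_k[2]; f1 <- f1_k[2]
    roc_auc <- auc_k[2]
  } else {
    precision <- mean(prec_k); recall <- mean(rec_k); f1 <- mean(f1_k)
    roc_auc <- mean(auc_k, na.rm = TRUE)
  }
  per_class <- data.frame(class = class_names, TP = tp, TN = tn, FP = fp,
                          FN = fn, precision = prec_k, recall = rec_k,
                          f1 = f1_k, roc_auc = auc_k, row.names = NULL)
  structure(list(accuracy = sum(tp) / N, precision = precision,
                 recall = recall, f1 = f1, roc_auc = roc_auc,
                 confusion = confusion, per_class = per_class, n = N),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> n=%d  accuracy=%.3f precision=%.3f recall=%.3f f1=%.3f roc_auc=%s\n",
    x$n, x$accuracy, x$precision, x$recall, x$f1,
    ifelse(is.na(x$roc_auc), "NA", sprintf("%.3f", x$roc_auc))))
  invisible(x)
}

# Flatten the headline metrics of a report to a named numeric vector.
.metric_vector <- function(m) {
  c(accuracy = m$accuracy, precision = m$precision, recall = m$recall,
    f1 = m$f1, roc_auc = m$roc_auc)
}
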