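#' Confusion matrix and classification metrics
#'
#' `confusion_matrix()` tabulates true classes (rows) against predictions
#' (columns). `compute_metrics()` derives the evaluation suite: global
#' accuracy; one-vs-rest precision, recall and F1 per class combined by
#' support-weighted averaging; and, when probability scores are supplied,
#' support-weighted one-vs-rest ROC AUC (trapezoidal). Support weighting is
#' the averaging scheme under which weighted recall is algebraically
#' identical to accuracy for single-label data — the reason recall equals
#' accuracy in this protocol's result tables — and micro-averaged F1 equals
#' accuracy as well.
#'
#' Classes absent from the true labels have undefined one-vs-rest terms; they
#' are dropped with a warning and the support weights renormalized. A
#' per-class precision with no predicted positives is taken as 0.
#'
#' @param truth,pred integer class codes `1..K` or factors over the same
#'   levels.
#' @param n_classes number of classes `K` (inferred from factors if missing).
#' @return `confusion_matrix()`: a K x K integer matrix.
#'   `compute_metrics()`: one-row data.frame with `accuracy`, `precision`,
#'   `recall`, `f1`, and `auc` (`NA` without scores).
#' @examples
#' cm <- confusion_matrix(c(1, 1, 2, 2, 3, 3), c(1, 2, 2, 2, 3, 1), 3)
#' compute_metrics(cm)   # accuracy 0.6667, precision 0.7222, f1 0.6556
#' @export
confusion_matrix <- function(truth, pred, n_classes = NULL) {
  if (is.factor(truth)) { if (is.null(n_classes)) n_classes <- nlevels(truth)
    truth <- as.integer(truth) }
  if (is.factor(pred)) pred <- as.integer(pred)
  if (is.null(n_classes)) n_classes <- max(truth, pred)
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(truth)) cm[truth[i], pred[i]] <- cm[truth[i], pred[i]] + 1L
  cm
}

#' @rdname confusion_matrix
#' @param cm a K x K confusion matrix (rows = truth).
#' @param scores optional N x K matrix of class probabilities (rows sum
#'   to 1) for the AUC.
#' @param labels true labels for the scored samples (required with `scores`).
#' @export
compute_metrics <- function(cm, scores = NULL, labels = NULL) {
  K <- nrow(cm)
  support <- rowSums(cm)
  present <- support > 0
  if (!all(present)) {
    warning("class(es) without true samples excluded from averaging: ",
            paste(which(!present), collapse = ", "))
  }
  w <- support[present] / sum(support[present])
  tp <- diag(cm)[present]
  fp <- colSums(cm)[present] - tp
  fn <- support[present] - tp
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- tp / (tp + fn)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  acc <- sum(diag(cm)) / sum(cm)
  auc <- NA_real_
  if (!is.null(scores)) {
    if (is.null(labels)) stop("labels are required to compute AUC from scores")
    if (is.factor(labels)) labels <- as.integer(labels)
    aucs <- vapply(which(present), function(k) {
      resp <- as.integer(labels == k)
      if (length(unique(resp)) < 2) return(NA_real_)
      as.numeric(pROC::auc(pROC::roc(resp, scores[, k], quiet = TRUE,
                                     direction = "<", levels = c(0, 1))))
    }, numeric(1))
    okc <- !is.na(aucs)
    auc <- sum(aucs[okc] * w[okc] / sum(w[okc]))
  }
  data.frame(accuracy = acc,
             precision = sum(w * prec),
             recall = sum(w * rec),
             f1 = sum(w * f1),
             auc = auc)
}

#' Evaluate a fitted model on a held-out index set
#'
#' Runs the model on the given samples and returns the metric suite together
#' with the confusion matrix, in the layout of the protocol's per-fold
#' result tables.
#'
#' @param object a fitted [ggenet_fit()] model.
#' @param x feature map of all samples, dim (N, 3, H, W).
#' @param y integer labels 1..K.
#' @param idx indices of the evaluation subset (default: all).
#' @return list with `metrics` (one-row data.frame) and `confusion` (K x K).
#' @export
evaluate <- function(object, x, y, idx = seq_along(y)) {
  probs <- predict(object, x[idx, , , , drop = FALSE], type = "prob")
  pred <- max.col(probs, ties.method = "first")
  K <- ncol(probs)
  cm <- confusion_matrix(y[idx], pred, K)
  list(metrics = compute_metrics(cm, probs, y[idx]), confusion = cm)
}

#' Per-fold report table
#'
#' Binds per-fold metric rows for one or more models into the standard
#' report: one row per fold per model plus a cross-fold `Average` row per
#' model.
#'
#' @param fold_metrics named list (per model) of data.frames with one metric
#'   row per fold.
#' @return data.frame with columns `fold`, `model`, and the metrics.
#' @export
fold_report <- function(fold_metrics) {
  out <- lapply(names(fold_metrics), function(m) {
    df <- fold_metrics[[m]]
    avg <- as.data.frame(lapply(df, function(col)
      if (is.numeric(col)) mean(col) else NA))
    df <- rbind(df, avg)
    data.frame(fold = c(seq_len(nrow(df) - 1), "Average"), model = m, df,
               row.names = NULL)
  })
  do.call(rbind, out)
}
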