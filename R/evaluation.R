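#' Confusion counts
#'
#' Partitions predictions into true/false positives/negatives; positives
#' are class 1 (PD).
#'
#' @param y_true,y_pred Equal-length binary (0/1) vectors.
#' @return A `confusion_counts` object (`tp`, `fp`, `tn`, `fn`).
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    dv_stop("dysvoice_error_length_mismatch",
            "y_true (%d) and y_pred (%d) differ", length(y_true), length(y_pred))
  }
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    dv_stop("dysvoice_error_not_binary", "labels must be 0/1")
  }
  structure(list(tp = sum(y_true == 1 & y_pred == 1),
                 fp = sum(y_true == 0 & y_pred == 1),
                 tn = sum(y_true == 0 & y_pred == 0),
                 fn = sum(y_true == 1 & y_pred == 0)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`, recall
#' (sensitivity) `TP/(TP+FN)`, specificity `TN/(TN+FP)`, F1
#' `2PR/(P+R)` and the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' A zero denominator yields `NA` for that metric together with its name in
#' `$undefined` — never a silent zero.
#'
#' @param c A `confusion_counts` object.
#' @return An `eval_metrics` list with the six metrics and `undefined`.
#' @export
metrics <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  total <- c$tp + c$tn + c$fp + c$fn
  if (total == 0) dv_stop("dysvoice_error_empty", "no evaluated items")
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- safe(c$tp, c$tp + c$fp)
  recall <- safe(c$tp, c$tp + c$fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  mcc_den <- sqrt(c$tp + c$fp) * sqrt(c$tp + c$fn) *
    sqrt(c$tn + c$fp) * sqrt(c$tn + c$fn)
  mcc <- if (mcc_den == 0) NA_real_ else
    (c$tp * c$tn - c$fp * c$fn) / mcc_den
  out <- list(accuracy = (c$tp + c$tn) / total,
              precision = precision, recall = recall,
              specificity = safe(c$tn, c$tn + c$fp),
              f1 = f1, mcc = mcc)
  out$undefined <- names(out)[vapply(out, function(v)
    length(v) == 1 && is.na(v), logical(1))]
  structure(out, class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  vals <- unlist(x[c("accuracy", "precision", "recall", "specificity",
                     "f1", "mcc")])
  cat("<eval_metrics>\n")
  print(round(vals, 4))
  if (length(x$undefined)) {
    cat("undefined (0/0):", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores (tied scores cross the threshold
#' together); AUC by the trapezoid rule, equivalent to the tie-corrected
#' Mann-Whitney statistic. Invariant under strictly monotone transforms of
#' the scores.
#'
#' @param y_true Binary labels.
#' @param scores Numeric classifier scores (higher = more positive).
#' @return A `roc_result`: `auc` and the `roc` data.frame of (fpr, tpr)
#'   points.
#' @export
roc_auc <- function(y_true, scores) {
  if (length(unique(y_true)) < 2) {
    dv_stop("dysvoice_error_one_class", "ROC needs both classes")
  }
  if (length(y_true) != length(scores)) {
    dv_stop("dysvoice_error_length_mismatch", "labels/scores differ in length")
  }
  n_pos <- sum(y_true == 1); n_neg <- sum(y_true == 0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(s) sum(scores >= s & y_true == 1), numeric(1)) / n_pos)
  fpr <- c(0, vapply(thr, function(s) sum(scores >= s & y_true == 0), numeric(1)) / n_neg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(list(auc = auc, roc = data.frame(fpr = fpr, tpr = tpr)),
            class = "roc_result")
}

#' Stratified k-fold cross-validation
#'
#' Algorithmic protocol: items are split into k stratified folds; each fold
#' serves once as the test set while a model is fitted on the remainder, so
#' every item is predicted exactly once out-of-fold. The primary report
#' pools the out-of-fold confusion; per-fold metrics (mean and sd) are
#' reported alongside.
#'
#' @param builder Function `(x_train, y_train) -> model` where the model
#'   supports [predict_proba()].
#' @param x Input batch: a matrix/data.frame of features (rows = items) or
#'   an array with items along the first dimension.
#' @param y Binary labels.
#' @param k Number of folds (default 10).
#' @param seed Fold-assignment seed.
#' @return An `eval_report`: pooled `metrics`, `auc`, `roc`, `folds`
#'   (per-fold metric rows), and out-of-fold `scores`.
#' @export
kfold_cv <- function(builder, x, y, k = 10, seed = 1) {
  y <- as.integer(y)
  n_min <- min(table(y))
  if (k < 2 || k > n_min) {
    dv_stop("dysvoice_error_bad_params",
            "k must lie in [2, smallest class size = %d]", n_min)
  }
  folds <- with_seed(seed, stratified_folds(y, k))
  take <- function(data, idx) {
    if (is.matrix(data) || is.data.frame(data)) data[idx, , drop = FALSE]
    else {
      d <- dim(data)
      arr <- array(data[slice.index(data, 1) %in% idx], c(length(idx), d[-1]))
      arr
    }
  }
  scores <- numeric(length(y))
  fold_rows <- vector("list", k)
  for (kk in seq_len(k)) {
    te <- which(folds == kk); tr <- which(folds != kk)
    model <- builder(take(x, tr), y[tr])
    p <- predict_proba(model, take(x, te))
    scores[te] <- p
    m <- metrics(confusion(y[te], as.integer(p >= 0.5)))
    fold_rows[[kk]] <- data.frame(fold = kk, accuracy = m$accuracy,
                                  f1 = m$f1, mcc = m$mcc)
  }
  pooled <- metrics(confusion(y, as.integer(scores >= 0.5)))
  roc <- roc_auc(y, scores)
  structure(list(metrics = pooled, auc = roc$auc, roc = roc$roc,
                 folds = do.call(rbind, fold_rows), scores = scores,
                 k = k, fold_assignment = folds),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s\n",
              if (!is.null(x$k)) sprintf("%d-fold CV (pooled)", x$k)
              else "held-out split"))
  print(x$metrics)
  cat(sprintf("AUC: %.4f\n", x$auc))
  invisible(x)
}

#' Evaluate a fitted model on held-out data
#'
#' @param model A model supporting [predict_proba()].
#' @param x Held-out inputs.
#' @param y Held-out binary labels.
#' @param threshold Decision threshold (default 0.5).
#' @return An `eval_report` (metrics, AUC, ROC, scores).
#' @export
evaluate_model <- function(model, x, y, threshold = 0.5) {
  p <- predict_proba(model, x)
  rep <- list(metrics = metrics(confusion(y, as.integer(p >= threshold))),
              scores = p)
  if (length(unique(y)) > 1) {
    roc <- roc_auc(y, p)
    rep$auc <- roc$auc; rep$roc <- roc$roc
  } else {
    rep$auc <- NA_real_
  }
  structure(rep, class = "eval_report")
}
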