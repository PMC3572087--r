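#' Confusion-matrix metric suite
#'
#' Computes the six headline metrics from the confusion counts:
#' sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision
#' `TP/(TP+FP)`, accuracy `(TP+TN)/n`, F1 `2*Pre*Sen/(Pre+Sen)`, and the
#' Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' Any 0/0 is defined as 0 (degenerate predictors score zero rather than
#' propagating NaN).
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return An object of class `metrics_report`: list with the four counts
#'   and `sen`, `spe`, `pre`, `f1`, `mcc`, `acc`.
#' @examples
#' confusion_metrics(tp = 3, fp = 1, tn = 4, fn = 2)
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  div0 <- function(num, den) if (den == 0) 0 else num / den
  sen <- div0(tp, tp + fn)
  spe <- div0(tn, tn + fp)
  pre <- div0(tp, tp + fp)
  acc <- div0(tp + tn, tp + tn + fp + fn)
  f1 <- div0(2 * pre * sen, pre + sen)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, sen = sen, spe = spe,
                 pre = pre, f1 = f1, mcc = mcc, acc = acc, auc = NA_real_),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report (TP=%d FP=%d TN=%d FN=%d)\n",
              x$tp, x$fp, x$tn, x$fn))
  v <- c(AUC = x$auc, Spe = x$spe, Pre = x$pre, Sen = x$sen,
         F1 = x$f1, MCC = x$mcc, ACC = x$acc)
  cat(paste(sprintf("%s=%.3f", names(v), v), collapse = "  "), "\n")
  invisible(x)
}

#' ROC curve and trapezoidal AUC
#'
#' Builds the ROC curve by sweeping every distinct score threshold (tied
#' scores are grouped into one step, giving the U-statistic half-credit tie
#' convention) and computes the area under it by the trapezoidal rule. The
#' result equals the Mann-Whitney probability that a random positive scores
#' above a random negative, ties counted half.
#'
#' @param scores Numeric prediction scores, larger = more positive.
#' @param labels `"positive"` / `"negative"` (or logical/0-1) per sample;
#'   both classes must be present.
#' @return List with `auc` and `roc`, a data frame of `(fpr, tpr)` points
#'   from (0,0) to (1,1).
#' @export
roc_auc <- function(scores, labels) {
  y <- normalize_labels(labels)
  if (length(unique(y)) < 2L) {
    stop("both classes must be present to build a ROC curve", call. = FALSE)
  }
  stopifnot(length(scores) == length(y))
  n_pos <- sum(y == "positive"); n_neg <- sum(y == "negative")
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- cumsum(vapply(thr, function(s) sum(scores == s & y == "positive"),
                      numeric(1)))
  fp <- cumsum(vapply(thr, function(s) sum(scores == s & y == "negative"),
                      numeric(1)))
  tpr <- c(0, tp / n_pos); fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(auc = auc, roc = data.frame(fpr = fpr, tpr = tpr))
}

normalize_labels <- function(labels) {
  if (is.logical(labels)) return(ifelse(labels, "positive", "negative"))
  if (is.numeric(labels)) return(ifelse(labels > 0, "positive", "negative"))
  labels <- as.character(labels)
  if (!all(labels %in% c("positive", "negative"))) {
    stop("labels must be 'positive'/'negative' (or logical/0-1)",
         call. = FALSE)
  }
  labels
}

#' Metrics from observed labels, predicted labels and scores
#'
#' @param labels Observed labels.
#' @param predicted Predicted class labels.
#' @param scores Prediction scores for the ROC/AUC (optional).
#' @return A `metrics_report` with `auc` and `roc` filled in when scores are
#'   given.
#' @export
evaluate_predictions <- function(labels, predicted, scores = NULL) {
  y <- normalize_labels(labels)
  yh <- normalize_labels(predicted)
  rep <- confusion_metrics(tp = sum(y == "positive" & yh == "positive"),
                           fp = sum(y == "negative" & yh == "positive"),
                           tn = sum(y == "negative" & yh == "negative"),
                           fn = sum(y == "positive" & yh == "negative"))
  if (!is.null(scores)) {
    r <- roc_auc(scores, y)
    rep$auc <- r$auc
    rep$roc <- r$roc
  }
  rep
}
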