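#' Confusion counts for binary labels
#'
#' Positive class is +1 (malignant by convention).
#'
#' @param truth,predicted vectors in {-1, +1} of equal length.
#' @return list(TP, FP, FN, TN).
#' @export
confusion_counts <- function(truth, predicted) {
  if (length(truth) != length(predicted)) stop("length mismatch")
  if (!all(c(truth, predicted) %in% c(-1, 1))) {
    stop("labels must be in {-1, +1}")
  }
  list(TP = sum(truth == 1 & predicted == 1),
       FP = sum(truth == -1 & predicted == 1),
       FN = sum(truth == 1 & predicted == -1),
       TN = sum(truth == -1 & predicted == -1))
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Binary classification metrics
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy (TP+TN)/total,
#' PPV TP/(TP+FP), NPV TN/(TN+FN), and the Matthews correlation coefficient
#' (TP*TN - FP*FN)/sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)). Any 0/0 metric is
#' reported as NA; MCC with a zero factor under the root is reported as 0.
#'
#' @param counts list with TP, FP, FN, TN (from [confusion_counts()]).
#' @return named list of the six metrics.
#' @export
binary_metrics <- function(counts) {
  with(counts, {
    if (any(c(TP, FP, FN, TN) < 0)) stop("negative counts")
    total <- TP + FP + FN + TN
    if (total == 0) stop("empty confusion matrix")
    mcc_den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
    list(
      sensitivity = safe_ratio(TP, TP + FN),
      specificity = safe_ratio(TN, TN + FP),
      accuracy = (TP + TN) / total,
      ppv = safe_ratio(TP, TP + FP),
      npv = safe_ratio(TN, TN + FN),
      mcc = if (mcc_den == 0) 0 else (TP * TN - FP * FN) / sqrt(mcc_den)
    )
  })
}

#' ROC curve and AUC
#'
#' TPR/FPR at every distinct score threshold (equal scores grouped), with
#' trapezoidal area. Equal scores across classes contribute half weight,
#' matching the pairwise concordance probability.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param truth labels in {-1, +1}, both classes present.
#' @return list(fpr, tpr, thresholds, auc).
#' @export
roc_auc <- function(scores, truth) {
  if (length(scores) != length(truth)) stop("length mismatch")
  if (length(unique(truth)) < 2L) stop("both classes must be present")
  pos <- truth == 1
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  fpr_full <- c(0, fpr)
  tpr_full <- c(0, tpr)
  if (fpr_full[length(fpr_full)] < 1 || tpr_full[length(tpr_full)] < 1) {
    fpr_full <- c(fpr_full, 1)
    tpr_full <- c(tpr_full, 1)
  }
  auc <- sum(diff(fpr_full) * (utils::head(tpr_full, -1) +
                                 utils::tail(tpr_full, -1)) / 2)
  list(fpr = fpr_full, tpr = tpr_full, thresholds = c(Inf, thr), auc = auc)
}

#' Write a metrics report as JSON and plain text
#'
#' @param metrics named list (e.g. [binary_metrics()] output plus auc).
#' @param json_path,txt_path output files (NULL to skip either).
#' @export
write_metrics_report <- function(metrics, json_path = NULL, txt_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(metrics, json_path, digits = NA, auto_unbox = TRUE,
                         na = "null")
  }
  if (!is.null(txt_path)) {
    lines <- sprintf("%-12s %s", names(metrics),
                     vapply(metrics, function(v)
                       if (is.na(v)) "undefined" else sprintf("%.4f", v),
                       character(1)))
    writeLines(lines, txt_path)
  }
  invisible(metrics)
}
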