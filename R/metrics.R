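#' Confusion counts for a binary classifier
#'
#' Standard 2x2 counts with respect to a chosen positive class.
#'
#' @param labels true class labels.
#' @param predictions predicted class labels, same length and coding.
#' @param positive_class the label treated as positive (default `1`,
#'   the ICU class under the Healthy = 0 / ICU = 1 convention).
#' @return An object of class `confusion_counts`: list with `TP`, `FP`,
#'   `TN`, `FN` and `n_total`.
#' @examples
#' confusion(c(1, 1, 0, 0), c(1, 1, 0, 0))
#' @export
confusion <- function(labels, predictions, positive_class = 1L) {
  if (length(labels) == 0L) stop("empty input")
  if (length(labels) != length(predictions))
    stop("labels and predictions must have equal length")
  pos_l <- labels == positive_class
  pos_p <- predictions == positive_class
  out <- list(TP = sum(pos_l & pos_p), FP = sum(!pos_l & pos_p),
              TN = sum(!pos_l & !pos_p), FN = sum(pos_l & !pos_p),
              n_total = length(labels))
  structure(lapply(out, as.integer), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion counts (n = %d): TP %d, FP %d, TN %d, FN %d\n",
              x$n_total, x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

metric_or_zero <- function(num, den, what) {
  if (den == 0) {
    warning("zero denominator in ", what, "; reporting 0")
    return(0)
  }
  num / den
}

one_vs_rest_metrics <- function(cc) {
  precision <- metric_or_zero(cc$TP, cc$TP + cc$FP, "precision")
  recall <- metric_or_zero(cc$TP, cc$TP + cc$FN, "recall")
  specificity <- metric_or_zero(cc$TN, cc$FP + cc$TN, "specificity")
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, specificity = specificity, f1 = f1)
}

#' Support-weighted binary classification metrics
#'
#' Computes one-vs-rest precision, recall (sensitivity), specificity and F1
#' per class and combines them weighted by class support
#' (`support_c / N`), plus overall accuracy `(TP + TN) / N`.  Support
#' weighting makes the weighted recall algebraically identical to the
#' overall accuracy.
#'
#' @param labels,predictions equal-length vectors of class labels.
#' @param classes the class levels; defaults to the sorted union observed.
#' @return Named list with `overall_accuracy`, `weighted_precision`,
#'   `weighted_recall`, `weighted_f1`, `weighted_specificity`, and the
#'   per-class `counts` (a list of `confusion_counts`).
#' @export
weighted_metrics <- function(labels, predictions, classes = NULL) {
  if (length(labels) == 0L) stop("empty input")
  if (is.null(classes)) classes <- sort(unique(c(labels, predictions)))
  n <- length(labels)
  per <- lapply(classes, function(cl) confusion(labels, predictions, cl))
  names(per) <- as.character(classes)
  supports <- vapply(classes, function(cl) sum(labels == cl), numeric(1))
  w <- supports / n
  mats <- vapply(per, one_vs_rest_metrics, numeric(4))
  list(overall_accuracy = sum(labels == predictions) / n,
       weighted_precision = sum(w * mats["precision", ]),
       weighted_recall = sum(w * mats["recall", ]),
       weighted_f1 = sum(w * mats["f1", ]),
       weighted_specificity = sum(w * mats["specificity", ]),
       supports = setNames(supports, as.character(classes)),
       counts = per)
}

#' ROC curve and area under the curve
#'
#' Sweeps a decision threshold over the unique scores (classifying as
#' positive when `score >= threshold`), computes the false positive rate
#' `FP / (FP + TN)` and true positive rate `TP / (TP + FN)` at each
#' threshold, and integrates the curve by the trapezoid rule.  The curve
#' runs monotonically from (0, 0) to (1, 1).
#'
#' @param scores positive-class scores (e.g. predicted ICU probabilities).
#' @param labels binary labels; `positive_class` marks the positive.
#' @param positive_class label treated as positive (default `1`).
#' @return List with `roc_points` (data frame `fpr`, `tpr`, `threshold`)
#'   and `auc`.
#' @export
roc_auc <- function(scores, labels, positive_class = 1L) {
  if (length(scores) != length(labels)) stop("scores and labels must align")
  pos <- labels == positive_class
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUC undefined: need at least one instance of each class")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) sum(scores >= t & pos) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !pos) / n_neg, numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1L) + tail(tpr, -1L)) / 2)
  list(roc_points = data.frame(fpr = fpr, tpr = tpr, threshold = thr),
       auc = auc)
}

#' Assemble a full classification report
#'
#' Bundles confusion counts, the support-weighted metrics and (when scores
#' are supplied) the ROC curve and AUC into one object.
#'
#' @param labels,predictions equal-length binary label vectors
#'   (Healthy = 0, ICU = 1 convention).
#' @param scores optional positive-class scores for the ROC analysis.
#' @param conf_level confidence level for the normal-approximation interval
#'   on the overall accuracy (default 0.90).
#' @return An object of class `classification_report`.
#' @export
classification_report <- function(labels, predictions, scores = NULL,
                                  conf_level = 0.90) {
  wm <- weighted_metrics(labels, predictions)
  roc <- if (!is.null(scores) && length(unique(labels)) > 1L)
    roc_auc(scores, labels) else NULL
  acc <- wm$overall_accuracy
  n <- length(labels)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  half <- z * sqrt(acc * (1 - acc) / n)
  structure(list(counts = wm$counts, supports = wm$supports,
                 overall_accuracy = acc,
                 accuracy_ci = c(max(0, acc - half), min(1, acc + half)),
                 conf_level = conf_level,
                 weighted_precision = wm$weighted_precision,
                 weighted_recall = wm$weighted_recall,
                 weighted_f1 = wm$weighted_f1,
                 weighted_specificity = wm$weighted_specificity,
                 roc_points = roc$roc_points, auc = roc$auc, n = n),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, digits = 4, ...) {
  cat(sprintf("Classification report (n = %d)\n", x$n))
  cat(sprintf("  overall accuracy:     %.*f  (%d%% CI %.*f-%.*f)\n", digits,
              x$overall_accuracy, round(100 * x$conf_level), digits,
              x$accuracy_ci[1], digits, x$accuracy_ci[2]))
  cat(sprintf("  weighted precision:   %.*f\n", digits, x$weighted_precision))
  cat(sprintf("  weighted recall:      %.*f\n", digits, x$weighted_recall))
  cat(sprintf("  weighted F1:          %.*f\n", digits, x$weighted_f1))
  cat(sprintf("  weighted specificity: %.*f\n", digits, x$weighted_specificity))
  if (!is.null(x$auc)) cat(sprintf("  ROC AUC:              %.*f\n", digits, x$auc))
  invisible(x)
}

#' ROC curve plot
#' @param x a `classification_report` with ROC points.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.classification_report <- function(x, ...) {
  if (is.null(x$roc_points)) stop("report has no ROC points (no scores supplied)")
  graphics::plot(x$roc_points$fpr, x$roc_points$tpr, type = "l",
                 xlab = "False positive rate (1 - specificity)",
                 ylab = "True positive rate (sensitivity)",
                 main = sprintf("ROC curve (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
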