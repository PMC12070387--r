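#' Confusion counts for binary predictions
#'
#' Tallies true/false positives and negatives for hard 0/1 predictions
#' against 0/1 reference labels.
#'
#' @param labels Integer or logical vector of reference labels (0/1).
#' @param predictions Integer or logical vector of predicted labels (0/1),
#'   same length as `labels`.
#' @return An object of class `confusion_counts`: a list with integer
#'   fields `tp`, `tn`, `fp`, `fn` summing to `length(labels)`.
#' @examples
#' confusion_counts(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
confusion_counts <- function(labels, predictions) {
  tt_assert(length(labels) == length(predictions) && length(labels) >= 1,
            "ShapeMismatchError",
            "labels and predictions must have equal positive length")
  labels <- as.integer(labels)
  predictions <- as.integer(predictions)
  tt_assert(all(labels %in% 0:1) && all(predictions %in% 0:1),
            "ShapeMismatchError", "labels and predictions must be binary 0/1")
  structure(
    list(
      tp = sum(labels == 1L & predictions == 1L),
      tn = sum(labels == 0L & predictions == 0L),
      fp = sum(labels == 0L & predictions == 1L),
      fn = sum(labels == 1L & predictions == 0L)
    ),
    class = "confusion_counts"
  )
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2 * precision * recall / (precision + recall)`; returns 0
#' when both inputs are 0.
#'
#' @param precision,recall Scalars in `[0, 1]`.
#' @return The F1 score in `[0, 1]`.
#' @examples
#' f1_score(0.933, 0.875)
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' Computes `accuracy = (TP + TN) / N`, `precision = TP / (TP + FP)`,
#' `recall = TP / (TP + FN)` and the F1 harmonic mean. Any 0/0 ratio (no
#' positive predictions, or no positive labels) is reported as 0 and the
#' affected metric names are listed in the `degenerate` field.
#'
#' @param counts A [confusion_counts] object.
#' @return An object of class `metric_report`: a list with `accuracy`,
#'   `precision`, `recall`, `f1` in `[0, 1]`, `auc` (`NA` until filled by
#'   [roc_auc]-based evaluation), `counts`, and a character vector
#'   `degenerate` naming metrics hit by the 0/0 convention.
#' @examples
#' compute_metrics(confusion_counts(c(1, 1, 0, 0), c(1, 1, 1, 0)))
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$tp + counts$tn + counts$fp + counts$fn
  tt_assert(total > 0, "EmptyEvalError", "no samples to evaluate")
  degenerate <- character(0)
  accuracy <- (counts$tp + counts$tn) / total
  if (counts$tp + counts$fp == 0) {
    precision <- 0
    degenerate <- c(degenerate, "precision")
  } else {
    precision <- counts$tp / (counts$tp + counts$fp)
  }
  if (counts$tp + counts$fn == 0) {
    recall <- 0
    degenerate <- c(degenerate, "recall")
  } else {
    recall <- counts$tp / (counts$tp + counts$fn)
  }
  if (precision + recall == 0) {
    f1 <- 0
    if (counts$tp == 0) degenerate <- c(degenerate, "f1")
  } else {
    f1 <- f1_score(precision, recall)
  }
  structure(
    list(accuracy = accuracy, precision = precision, recall = recall,
         f1 = f1, auc = NA_real_, counts = counts, degenerate = degenerate),
    class = "metric_report"
  )
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the unique predicted scores in
#' descending order (tied scores form a single step) and integrates the
#' resulting (FPR, TPR) polyline by the trapezoidal rule. The AUC equals the
#' Mann-Whitney concordance probability.
#'
#' @param labels Binary 0/1 reference labels; both classes must occur.
#' @param scores Numeric scores (e.g. predicted probabilities), higher
#'   meaning more positive.
#' @return An object of class `roc_curve`: a list with `points` (a
#'   data.frame of `fpr`, `tpr`, `threshold` starting at (0, 0) and ending
#'   at (1, 1)) and the scalar `auc`.
#' @examples
#' roc_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))
#' @export
roc_auc <- function(labels, scores) {
  tt_assert(length(labels) == length(scores) && length(labels) >= 2,
            "ShapeMismatchError", "labels and scores must have equal length >= 2")
  labels <- as.integer(labels)
  tt_assert(all(labels %in% 0:1), "RocError", "labels must be binary 0/1")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  tt_assert(n_pos > 0 && n_neg > 0, "RocError",
            "both classes must be present to compute a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # collapse tied scores into one threshold step
  last_of_group <- c(s[-length(s)] != s[-1], TRUE)
  tp <- cumsum(y)[last_of_group]
  fp <- cumsum(1L - y)[last_of_group]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  thr <- c(Inf, s[last_of_group])
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(
    list(points = data.frame(fpr = fpr, tpr = tpr, threshold = thr),
         auc = auc),
    class = "roc_curve"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("Confusion counts:\n")
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2,
              dimnames = list(c("label 1", "label 0"),
                              c("pred 1", "pred 0")))
  print(m)
  invisible(x)
}

#' @export
print.metric_report <- function(x, digits = 3, ...) {
  cat("Binary classification metrics",
      sprintf("(n = %d)\n", x$counts$tp + x$counts$tn + x$counts$fp + x$counts$fn))
  vals <- c(accuracy = x$accuracy, precision = x$precision,
            recall = x$recall, f1 = x$f1, auc = x$auc)
  print(round(vals, digits))
  if (length(x$degenerate)) {
    cat("0/0 convention applied to:", paste(x$degenerate, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.metric_report <- function(x, ...) {
  data.frame(accuracy = x$accuracy, precision = x$precision,
             recall = x$recall, f1 = x$f1, auc = x$auc,
             tp = x$counts$tp, tn = x$counts$tn,
             fp = x$counts$fp, fn = x$counts$fn)
}

#' Write a metric report to CSV and/or JSON
#'
#' @param report A `metric_report`.
#' @param csv,json Optional output paths; either may be `NULL`.
#' @return The report, invisibly.
#' @export
write_metric_report <- function(report, csv = NULL, json = NULL) {
  stopifnot(inherits(report, "metric_report"))
  df <- as.data.frame(report)
  if (!is.null(csv)) utils::write.csv(df, csv, row.names = FALSE)
  if (!is.null(json)) {
    jsonlite::write_json(as.list(df), json, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "l",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
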