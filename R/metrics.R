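#' Confusion matrix
#'
#' `counts[t, p]` is the number of samples with true class `t` predicted as
#' class `p` (0-based labels, rows = truth).
#'
#' @param true_labels,predicted_labels Equal-length integer vectors with
#'   values in `[0, num_classes)`.
#' @param num_classes Number of classes.
#' @return A `confusion_matrix`: an integer `num_classes x num_classes`
#'   matrix with class labels as dimnames.
#' @export
confusion_matrix <- function(true_labels, predicted_labels, num_classes) {
  num_classes <- check_number(num_classes, "num_classes", 1, integer = TRUE)
  if (length(true_labels) != length(predicted_labels))
    stop_validation("label vectors must have equal length")
  labs <- c(true_labels, predicted_labels)
  if (length(labs) && (any(labs != round(labs)) || any(labs < 0) ||
                       any(labs >= num_classes)))
    stop_validation("labels must be integers in [0, %d)", num_classes)
  lev <- seq_len(num_classes) - 1L
  cm <- table(factor(true_labels, levels = lev),
              factor(predicted_labels, levels = lev))
  cm <- unclass(matrix(as.integer(cm), num_classes, num_classes,
                       dimnames = list(true = lev, predicted = lev)))
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Classification metrics from a confusion matrix
#'
#' Reduces the matrix one-vs-rest per class: `TP` the diagonal entry, `FP`
#' the rest of the column, `FN` the rest of the row, `TN` the remainder.
#' Per class, `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)` and `F1` is
#' their harmonic mean.  Aggregates are macro-averaged (unweighted mean over
#' classes); `accuracy` is micro (`trace / total`).  A class whose
#' denominator is zero gets metric 0 and is flagged in `undefined`.
#'
#' @param cm A [confusion_matrix()] (or plain square count matrix).
#' @return An `eval_report`: list with `per_class` data frame (precision,
#'   recall, f1, support, flags), `macro_precision`, `macro_recall`,
#'   `macro_f1`, `accuracy` and the confusion matrix.
#' @examples
#' cm <- confusion_matrix(c(0, 0, 1, 1), c(0, 1, 1, 1), 2)
#' metrics_from_confusion(cm)$accuracy # 0.75
#' @export
metrics_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm) || any(cm < 0))
    stop_validation("`cm` must be a square non-negative count matrix")
  total <- sum(cm)
  if (total < 1) stop_validation("confusion matrix is empty")
  k <- nrow(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  undefined_p <- tp + fp == 0
  undefined_r <- tp + fn == 0
  per_class <- data.frame(class = seq_len(k) - 1L,
                          precision = precision, recall = recall, f1 = f1,
                          support = rowSums(cm),
                          precision_undefined = undefined_p,
                          recall_undefined = undefined_r,
                          row.names = NULL)
  structure(list(per_class = per_class,
                 macro_precision = mean(precision),
                 macro_recall = mean(recall),
                 macro_f1 = mean(f1),
                 accuracy = sum(tp) / total,
                 confusion = cm),
            class = "eval_report")
}

#' Evaluate predictions directly
#'
#' Convenience wrapper: builds the confusion matrix from label vectors and
#' computes the [metrics_from_confusion()] report.
#'
#' @inheritParams confusion_matrix
#' @return An `eval_report`.
#' @export
evaluate_predictions <- function(true_labels, predicted_labels, num_classes) {
  metrics_from_confusion(
    confusion_matrix(true_labels, predicted_labels, num_classes))
}

#' @export
print.eval_report <- function(x, digits = 4L, ...) {
  cat(sprintf("<eval_report> %d classes, %d samples\n",
              nrow(x$confusion), sum(x$confusion)))
  cat(sprintf("  accuracy        %.*f\n", digits, x$accuracy))
  cat(sprintf("  macro precision %.*f\n", digits, x$macro_precision))
  cat(sprintf("  macro recall    %.*f\n", digits, x$macro_recall))
  cat(sprintf("  macro F1        %.*f\n", digits, x$macro_f1))
  invisible(x)
}
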