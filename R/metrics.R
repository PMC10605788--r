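# Confusion matrix and per-class / weighted precision, recall, F1,
# accuracy.
#
# Orientation note: rows index the actual class and columns the
# predicted class. Conventionally, recall of class i is the i-th
# row-normalized diagonal and precision the column-normalized one; the
# `paper_literal` flag swaps the two definitions for reproducing
# reports that use the transposed indexing.

#' Confusion matrix from label vectors
#'
#' @param y_true,y_pred Equal-length vectors of 0-based class ordinals
#'   (canonical surface order).
#' @param n_classes Number of classes.
#' @return Integer `n_classes x n_classes` matrix, rows = actual,
#'   columns = predicted, dimnames in canonical surface order when
#'   `n_classes` is 9.
#' @export
confusion <- function(y_true, y_pred, n_classes = 9) {
  if (length(y_true) != length(y_pred))
    stop("confusion: label vectors differ in length")
  if (length(y_true) &&
      (min(y_true, y_pred) < 0 || max(y_true, y_pred) >= n_classes))
    stop("confusion: label outside [0, ", n_classes, ")")
  lv <- 0:(n_classes - 1)
  cm <- table(factor(y_true, levels = lv), factor(y_pred, levels = lv))
  cm <- matrix(as.integer(cm), n_classes, n_classes)
  nm <- if (n_classes == 9) surface_levels() else as.character(lv)
  dimnames(cm) <- list(actual = nm, predicted = nm)
  cm
}

#' Per-class precision, recall and F1
#'
#' With rows = actual classes: recall_i is the diagonal over the row
#' sum, precision_i the diagonal over the column sum, and F1 their
#' harmonic mean; 0/0 is defined as 0 (degenerate classes trigger a
#' warning).
#'
#' @param cm Confusion matrix (rows = actual).
#' @param paper_literal Swap the row/column roles of precision and
#'   recall (the transposed-index convention).
#' @return data.frame with columns `class`, `precision`, `recall`,
#'   `f1`, `support`.
#' @export
per_class_metrics <- function(cm, paper_literal = FALSE) {
  cm <- as.matrix(cm)
  diagc <- diag(cm)
  rows <- rowSums(cm)
  cols <- colSums(cm)
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  re <- safe_div(diagc, rows)
  pr <- safe_div(diagc, cols)
  if (paper_literal) { tmp <- pr; pr <- re; re <- tmp }
  if (any(rows == 0) || any(cols == 0))
    warning("per_class_metrics: degenerate class (empty row or column); ",
            "0/0 reported as 0")
  f1 <- ifelse(pr + re > 0, 2 * pr * re / (pr + re), 0)
  data.frame(class = rownames(cm) %||% as.character(seq_along(diagc) - 1),
             precision = pr, recall = re, f1 = f1, support = rows,
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Weighted precision, recall, F1 and accuracy
#'
#' Weighted averages of the per-class metrics with weights equal to
#' each class's actual sample count (row sums); accuracy is the trace
#' over the total. When the weights are the actual-class counts,
#' weighted recall equals accuracy identically.
#'
#' @inheritParams per_class_metrics
#' @return List with `precision`, `recall`, `f1`, `accuracy`.
#' @export
weighted_metrics <- function(cm, paper_literal = FALSE) {
  cm <- as.matrix(cm)
  total <- sum(cm)
  if (total == 0) stop("weighted_metrics: empty confusion matrix")
  pc <- suppressWarnings(per_class_metrics(cm, paper_literal = paper_literal))
  w <- pc$support / total
  list(precision = sum(w * pc$precision),
       recall = sum(w * pc$recall),
       f1 = sum(w * pc$f1),
       accuracy = sum(diag(cm)) / total)
}

#' Row-normalize a confusion matrix
#'
#' Divides each row by its sum (zero rows stay zero); the diagonal of
#' the result is the per-class recall.
#'
#' @param cm Confusion matrix (rows = actual).
#' @return Numeric matrix of row proportions.
#' @export
row_normalized <- function(cm) {
  cm <- as.matrix(cm)
  rs <- rowSums(cm)
  out <- cm / ifelse(rs > 0, rs, 1)
  out[rs == 0, ] <- 0
  out
}

#' Full metrics report for a pair of label vectors
#'
#' @inheritParams confusion
#' @param paper_literal See [per_class_metrics()].
#' @return List with `confusion`, `per_class`, `weighted` and
#'   `accuracy`.
#' @export
metrics_report <- function(y_true, y_pred, n_classes = 9,
                           paper_literal = FALSE) {
  cm <- confusion(y_true, y_pred, n_classes)
  w <- weighted_metrics(cm, paper_literal)
  list(confusion = cm,
       per_class = suppressWarnings(per_class_metrics(cm, paper_literal)),
       weighted = w, accuracy = w$accuracy)
}
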