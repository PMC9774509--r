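#' Multiclass evaluation report
#'
#' Builds the confusion matrix (rows = true class, columns = predicted) and
#' the one-vs-rest counts TP, TN, FP, FN per class, from which the four
#' standard indexes follow:
#' accuracy \eqn{(TP+TN)/(TP+TN+FP+FN)}, precision \eqn{TP/(TP+FP)},
#' recall \eqn{TP/(TP+FN)} and their harmonic mean F1. Macro averages are
#' unweighted means over classes. Note that macro accuracy is computed
#' one-vs-rest and is therefore inflated by true negatives relative to
#' overall accuracy (the confusion-matrix trace over the total) — both are
#' reported and labelled distinctly. A class never predicted has its
#' precision defined as 0 and is flagged.
#'
#' @param truth,predicted Equal-length integer label vectors in
#'   `[0, n_classes)`.
#' @param n_classes Number of classes.
#' @return Object of class `koi_eval`: `confusion` matrix, `per_class`
#'   tibble (counts and metrics per class), `overall_accuracy`,
#'   `macro` tibble, `flagged_classes` (zero predicted positives).
#' @examples
#' evaluate_predictions(c(0, 1, 2, 2), c(0, 1, 2, 1), 3)
#' @export
evaluate_predictions <- function(truth, predicted, n_classes) {
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  if (length(truth) != length(predicted)) {
    stop_koi("Label vectors must have equal length.", "koi_argument_error")
  }
  if (any(c(truth, predicted) < 0) || any(c(truth, predicted) >= n_classes)) {
    stop_koi("Labels outside [0, n_classes).", "koi_label_error")
  }
  lv <- factor(truth, levels = 0:(n_classes - 1))
  pv <- factor(predicted, levels = 0:(n_classes - 1))
  confusion <- table(truth = lv, predicted = pv)
  confusion <- matrix(as.integer(confusion), n_classes, n_classes,
                      dimnames = list(true = 0:(n_classes - 1),
                                      predicted = 0:(n_classes - 1)))
  total <- length(truth)
  per_class <- purrr::map_dfr(seq_len(n_classes), function(c1) {
    tp <- confusion[c1, c1]
    fp <- sum(confusion[, c1]) - tp
    fn <- sum(confusion[c1, ]) - tp
    tn <- total - tp - fp - fn
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    tibble::tibble(class_id = c1 - 1L, tp = tp, tn = tn, fp = fp, fn = fn,
                   accuracy = (tp + tn) / total, precision = prec,
                   recall = rec, f1 = f1)
  })
  macro <- per_class |>
    dplyr::summarise(dplyr::across(c("accuracy", "precision", "recall", "f1"),
                                   mean))
  structure(list(
    confusion = confusion,
    per_class = per_class,
    overall_accuracy = sum(diag(confusion)) / total,
    macro = macro,
    flagged_classes = per_class$class_id[per_class$tp + per_class$fp == 0],
    n = total
  ), class = "koi_eval")
}

#' @export
print.koi_eval <- function(x, ...) {
  cat(sprintf("<koi_eval> n=%d overall accuracy %.4f | macro P=%.4f R=%.4f F1=%.4f\n",
              x$n, x$overall_accuracy, x$macro$precision, x$macro$recall,
              x$macro$f1))
  invisible(x)
}

#' @rdname evaluate_predictions
#' @param x A `koi_eval`.
#' @param ... Unused.
#' @method tidy koi_eval
#' @export
tidy.koi_eval <- function(x, ...) x$per_class

#' @rdname evaluate_predictions
#' @method glance koi_eval
#' @export
glance.koi_eval <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    overall_accuracy = x$overall_accuracy,
    macro_accuracy = x$macro$accuracy,
    macro_precision = x$macro$precision,
    macro_recall = x$macro$recall,
    macro_f1 = x$macro$f1
  )
}
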