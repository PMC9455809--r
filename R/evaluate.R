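# Confusion-matrix metrics under the inter-patient protocol: per-class
# precision, recall, F1 and the macro-averaged F1 (the unweighted mean
# of per-class F1 over the classes present in the ground truth), plus
# overall accuracy.

#' Evaluate predictions against ground truth
#'
#' Precision is TP over predicted positives, recall TP over true
#' positives, `f1 = 2 p r / (p + r)` with the 0/0 convention mapping
#' to 0. Macro-F1 averages F1 over the classes present in the ground
#' truth; a class that is only predicted (absent from the truth) still
#' appears in the confusion matrix but does not enter the macro
#' average.
#'
#' @param truth Ground-truth class labels.
#' @param pred Predicted class labels (same length).
#' @param classes Optional class ordering for the confusion matrix.
#' @return An `eval_report`: list with `confusion` (matrix, rows =
#'   truth), `per_class` (tibble: class, support, precision, recall,
#'   f1), `macro_f1`, `accuracy`, `n`.
#' @export
evaluate_predictions <- function(truth, pred, classes = NULL) {
  truth <- as.character(truth); pred <- as.character(pred)
  stopifnot(length(truth) == length(pred), length(truth) > 0)
  if (is.null(classes)) classes <- sort(union(truth, pred))
  cm <- table(factor(truth, levels = classes),
              factor(pred, levels = classes))
  cm <- unclass(cm)
  names(dimnames(cm)) <- c("truth", "pred")
  tp <- diag(cm)
  p_denom <- colSums(cm)
  r_denom <- rowSums(cm)
  precision <- ifelse(p_denom > 0, tp / p_denom, 0)
  recall <- ifelse(r_denom > 0, tp / r_denom, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  present <- classes[classes %in% truth]
  per_class <- tibble::tibble(
    class = classes, support = as.numeric(r_denom),
    precision = as.numeric(precision), recall = as.numeric(recall),
    f1 = as.numeric(f1))
  structure(list(
    confusion = cm, per_class = per_class,
    macro_f1 = mean(f1[match(present, classes)]),
    accuracy = sum(tp) / length(truth),
    n = length(truth)), class = "eval_report")
}

#' Macro-averaged F1 score
#'
#' @inheritParams evaluate_predictions
#' @return Scalar macro-F1 in `[0, 1]`.
#' @export
macro_f1 <- function(truth, pred) {
  evaluate_predictions(truth, pred)$macro_f1
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: n=%d, accuracy=%.3f, macro-F1=%.3f>\n",
              x$n, x$accuracy, x$macro_f1))
  print(x$confusion)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-class metrics of an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return Tibble with one row per class: `class`, `support`,
#'   `precision`, `recall`, `f1`.
#' @export
tidy.eval_report <- function(x, ...) {
  x$per_class
}

#' One-row summary of an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return Tibble with `n`, `accuracy`, `macro_f1`.
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(n = x$n, accuracy = x$accuracy, macro_f1 = x$macro_f1)
}

#' Confusion-matrix heatmap
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("truth", "pred", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "predicted class", y = "true class",
                  title = sprintf("accuracy %.3f, macro-F1 %.3f",
                                  object$accuracy, object$macro_f1)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
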