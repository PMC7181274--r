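#' Confusion matrix
#'
#' Tabulates predictions against truth: `counts[i, j]` is the number of
#' samples with true class `i - 1` predicted as class `j - 1` (classes are
#' 0-based in the API, rows/columns 1-based in R).
#'
#' @param y_true,y_pred 0-based integer label vectors of equal length.
#' @param n_classes Number of declared classes n (labels must lie in `[0, n)`).
#' @return Object of class `confusion_matrix`: list with `counts` (`[n x n]`),
#'   `n_classes`, `N`.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes) {
  if (length(y_true) != length(y_pred))
    stop_invalid("y_true and y_pred must have equal length")
  if (length(y_true) > 0 &&
      (any(y_true < 0 | y_true >= n_classes) ||
       any(y_pred < 0 | y_pred >= n_classes)))
    stop_invalid("labels out of range [0, n_classes)")
  counts <- matrix(0L, n_classes, n_classes,
                   dimnames = list(true = 0:(n_classes - 1),
                                   pred = 0:(n_classes - 1)))
  if (length(y_true) > 0) {
    tab <- table(factor(y_true, levels = 0:(n_classes - 1)),
                 factor(y_pred, levels = 0:(n_classes - 1)))
    counts[] <- as.integer(tab)
  }
  structure(list(counts = counts, n_classes = as.integer(n_classes),
                 N = length(y_true)),
            class = "confusion_matrix")
}

# per-class TP/FP/FN and derived precision/recall/F1 (0/0 terms -> 0)
per_class_stats <- function(cm) {
  counts <- cm$counts
  tp <- diag(counts)
  fp <- colSums(counts) - tp
  fn <- rowSums(counts) - tp
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
       f1 = f1, n_c = rowSums(counts))
}

#' Weighted F1-score
#'
#' Class-size-weighted mean of per-class F1: `F_w = sum_c w_c * F1_c` with
#' `w_c = n_c / N`, where `F1_c = 2 * precision_c * recall_c /
#' (precision_c + recall_c)` and a class's term is 0 when its precision and
#' recall are both 0. Robust to the heavy class imbalance (dominant NULL
#' class) typical of activity datasets.
#'
#' @param cm A [confusion_matrix()].
#' @return `F_w` in `[0, 1]`.
#' @export
weighted_f1 <- function(cm) {
  if (cm$N == 0) stop_invalid("metric undefined for an empty confusion matrix")
  st <- per_class_stats(cm)
  sum((st$n_c / cm$N) * st$f1)
}

#' Average (macro) F1-score
#'
#' Unweighted mean of per-class F1 over all n declared classes (classes absent
#' from the data contribute 0), hence independent of the class distribution:
#' `F_m = (2/|c|) sum_c precision_c * recall_c / (precision_c + recall_c)`.
#'
#' @param cm A [confusion_matrix()].
#' @return `F_m` in `[0, 1]`.
#' @export
average_f1 <- function(cm) {
  if (cm$N == 0) stop_invalid("metric undefined for an empty confusion matrix")
  st <- per_class_stats(cm)
  mean(st$f1)
}

#' Overall accuracy
#'
#' @param cm A [confusion_matrix()].
#' @return `trace / N` in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  if (cm$N == 0) stop_invalid("metric undefined for an empty confusion matrix")
  sum(diag(cm$counts)) / cm$N
}

#' Full evaluation report
#'
#' @param cm A [confusion_matrix()].
#' @return List with `accuracy`, `weighted_f1`, `average_f1` and a per-class
#'   data frame (`class`, `n`, `precision`, `recall`, `f1`).
#' @export
metrics_report <- function(cm) {
  st <- per_class_stats(cm)
  list(accuracy = accuracy(cm),
       weighted_f1 = weighted_f1(cm),
       average_f1 = average_f1(cm),
       per_class = data.frame(class = 0:(cm$n_classes - 1), n = st$n_c,
                              precision = st$precision, recall = st$recall,
                              f1 = st$f1, row.names = NULL))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %d classes, N = %d\n", x$n_classes, x$N))
  print(x$counts)
  invisible(x)
}
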