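#' Classification metrics from one-vs-rest counts
#'
#' Per class c the one-vs-rest counts are TP (true c predicted c), FP
#' (other predicted c), FN (true c predicted other), TN (the rest); from
#' these, precision `P = TP/(TP+FP)`, recall `R = TP/(TP+FN)` and
#' `F1S = 2TP/(2TP+FP+FN)`, reported as percentages. Overall accuracy is
#' the micro form correct/total, equal to trace(confusion)/sum(confusion).
#' Degenerate denominators give 0 with a warning.
#'
#' @param y_true,y_pred equal-length integer vectors of labels in
#'   1..n_classes (or factors with identical levels).
#' @param n_classes number of classes; default inferred.
#' @return object of class `metrics_report`: list with `confusion`
#'   (n x n matrix, rows = true), `per_class` (data.frame with TP, FP,
#'   FN, TN, P, R, F1S) and `accuracy` (percent).
#' @export
compute_metrics <- function(y_true, y_pred, n_classes = NULL) {
  if (is.factor(y_true)) y_true <- as.integer(y_true)
  if (is.factor(y_pred)) y_pred <- as.integer(y_pred)
  stopifnot(length(y_true) == length(y_pred), length(y_true) > 0)
  n_classes <- n_classes %||% max(y_true, y_pred)
  conf <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(y_true)) {
    conf[y_true[i], y_pred[i]] <- conf[y_true[i], y_pred[i]] + 1L
  }
  total <- sum(conf)
  per <- data.frame(class = seq_len(n_classes), TP = 0L, FP = 0L,
                    FN = 0L, TN = 0L, P = 0, R = 0, F1S = 0)
  for (cl in seq_len(n_classes)) {
    tp <- conf[cl, cl]
    fp <- sum(conf[-cl, cl])
    fn <- sum(conf[cl, -cl])
    tn <- total - tp - fp - fn
    per$TP[cl] <- tp; per$FP[cl] <- fp; per$FN[cl] <- fn; per$TN[cl] <- tn
    per$P[cl] <- safe_ratio(tp, tp + fp, sprintf("class %d precision", cl))
    per$R[cl] <- safe_ratio(tp, tp + fn, sprintf("class %d recall", cl))
    per$F1S[cl] <- safe_ratio(2 * tp, 2 * tp + fp + fn,
                              sprintf("class %d F1S", cl))
  }
  structure(list(confusion = conf, per_class = per,
                 accuracy = 100 * sum(diag(conf)) / total),
            class = "metrics_report")
}

safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(what, ": denominator is zero, reporting 0", call. = FALSE)
    return(0)
  }
  100 * num / den
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Confusion matrix (rows = true):\n")
  print(x$confusion)
  cat("\nPer-class one-vs-rest metrics (%):\n")
  print(transform(x$per_class, P = round(P, 2), R = round(R, 2),
                  F1S = round(F1S, 2)), row.names = FALSE)
  cat(sprintf("\nOverall accuracy: %.2f%%\n", x$accuracy))
  invisible(x)
}
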