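# Confusion-matrix metrics: accuracy, per-class and macro P/R/F1, and the
# (multiclass) Matthews correlation coefficient.

#' Confusion matrix
#'
#' @param y_true,y_pred Integer vectors of 0-based class labels.
#' @param C Number of classes.
#' @return C x C integer matrix of counts; rows are true classes, columns
#'   predicted classes.
#' @export
confusion_matrix <- function(y_true, y_pred, C) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (any(y_true < 0L | y_true >= C) || any(y_pred < 0L | y_pred >= C)) {
    stop("label out of range [0, C)")
  }
  cm <- matrix(0L, C, C)
  for (i in seq_along(y_true)) {
    cm[y_true[[i]] + 1L, y_pred[[i]] + 1L] <- cm[y_true[[i]] + 1L, y_pred[[i]] + 1L] + 1L
  }
  cm
}

#' Classification metrics from a confusion matrix
#'
#' Per-class precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and F1 (harmonic
#' mean), with the 0/0 -> 0 convention for undefined cells; macro metrics
#' are unweighted means over classes. Also includes accuracy and the
#' Matthews correlation coefficient ([mcc()]).
#'
#' @param cm Square confusion matrix of counts (rows true, columns
#'   predicted).
#' @return An object of class `metrics_report`: list with `confusion`,
#'   `accuracy`, `precision`/`recall`/`f1` (per-class vectors),
#'   `macro_precision`, `macro_recall`, `macro_f1`, `mcc`, `n`.
#' @export
classification_metrics <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm) || nrow(cm) == 0L) stop("confusion matrix must be square and non-empty")
  if (any(cm < 0)) stop("negative counts")
  total <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  prec <- safe_div(tp, tp + fp)
  rec <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * prec * rec, prec + rec)
  structure(list(
    confusion = cm,
    accuracy = if (total > 0) sum(tp) / total else 0,
    precision = prec, recall = rec, f1 = f1,
    macro_precision = mean(prec), macro_recall = mean(rec),
    macro_f1 = mean(f1),
    mcc = mcc(cm),
    n = total), class = "metrics_report")
}

#' Matthews correlation coefficient
#'
#' For two classes this is the familiar
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. For more classes
#' the covariance-form multiclass generalization is used,
#' `(N*tr(C) - sum_k t_k p_k) / sqrt((N^2 - sum p_k^2)(N^2 - sum t_k^2))`
#' with `t_k`/`p_k` the true/predicted class totals; it reduces exactly to
#' the binary formula at C = 2. A zero denominator returns 0.
#'
#' @param cm Square confusion matrix (rows true, columns predicted).
#' @return Numeric scalar in [-1, 1].
#' @export
mcc <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  n <- sum(cm)
  t_k <- rowSums(cm)
  p_k <- colSums(cm)
  num <- n * sum(diag(cm)) - sum(t_k * p_k)
  den <- sqrt((n^2 - sum(p_k^2)) * (n^2 - sum(t_k^2)))
  if (den == 0) return(0)
  num / den
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> n=", x$n, "\n", sep = "")
  cat(sprintf("  accuracy %.4f | macro P %.4f R %.4f F1 %.4f | MCC %.4f\n",
              x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1, x$mcc))
  invisible(x)
}

#' Serialize a metrics report
#'
#' `metrics_to_json` writes the full report with stable key names;
#' `metrics_to_csv_row` emits the one-row summary table
#' (accuracy, precision, recall, macro F1, MCC).
#'
#' @param report A [classification_metrics()] report.
#' @param path Optional file path; when `NULL` the JSON string / data frame
#'   is returned.
#' @return JSON string (or `path`), and a one-row data frame respectively.
#' @export
metrics_to_json <- function(report, path = NULL) {
  obj <- list(confusion = unclass(report$confusion),
              accuracy = report$accuracy,
              precision = report$precision, recall = report$recall,
              f1 = report$f1,
              macro_precision = report$macro_precision,
              macro_recall = report$macro_recall,
              macro_f1 = report$macro_f1,
              mcc = report$mcc, n = report$n)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname metrics_to_json
#' @export
metrics_to_csv_row <- function(report, path = NULL) {
  df <- data.frame(accuracy = report$accuracy,
                   precision = report$macro_precision,
                   recall = report$macro_recall,
                   macro_f1 = report$macro_f1,
                   mcc = report$mcc)
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(path))
  }
  df
}

#' Stratify sequences by length quartiles
#'
#' Assigns each sequence to a `short` / `middle` / `long` bin using the
#' first and third quartiles of the length distribution (computed with the
#' linear-interpolation quantile convention): below Q1 is short, above Q3 is
#' long, inclusive in between.
#'
#' @param sequence_lengths Numeric vector of at least 4 lengths.
#' @return Factor of bin labels with levels `short`, `middle`, `long`.
#' @export
length_stratify <- function(sequence_lengths) {
  if (length(sequence_lengths) < 4L) stop("need at least 4 lengths")
  q <- stats::quantile(sequence_lengths, c(0.25, 0.75), names = FALSE, type = 7)
  bin <- ifelse(sequence_lengths < q[[1L]], "short",
                ifelse(sequence_lengths > q[[2L]], "long", "middle"))
  factor(bin, levels = c("short", "middle", "long"))
}
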