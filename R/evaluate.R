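# Confusion matrix and one-vs-rest multiclass metrics: accuracy,
# sensitivity, specificity, precision, F-measure; macro averages are
# unweighted means over classes.

#' Confusion matrix from true and predicted codes
#'
#' Entry (i, j) counts documents of true class i predicted as class j.
#'
#' @param y_true,y_pred integer 0-based class codes of equal length.
#' @param K number of classes.
#' @param class_names optional class names (length K).
#' @return an object of class `confusion_matrix`: K x K integer matrix
#'   with class-name dimnames.
#' @export
confusion <- function(y_true, y_pred, K, class_names = NULL) {
  fail_if(length(y_true) != length(y_pred),
          "y_true and y_pred must have equal length")
  fail_if(length(y_true) > 0 &&
            (min(c(y_true, y_pred)) < 0 || max(c(y_true, y_pred)) >= K),
          "class code out of range 0..K-1")
  if (is.null(class_names)) class_names <- as.character(seq_len(K) - 1L)
  cm <- matrix(0L, K, K, dimnames = list(true = class_names,
                                         predicted = class_names))
  for (i in seq_along(y_true))
    cm[y_true[i] + 1L, y_pred[i] + 1L] <- cm[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Metrics from a confusion matrix
#'
#' Each class is scored one-vs-rest: TP is the diagonal entry, FN the
#' rest of its row, FP the rest of its column, TN everything else.
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), precision =
#' TP/(TP+FP), F = 2·precision·sensitivity/(precision+sensitivity).
#' Ratios of the form 0/0 are reported as 0 and flagged in the
#' `undefined` column (they signal a degenerate class, not performance).
#' Macro metrics are unweighted class means; overall accuracy is
#' trace/total.
#'
#' @param cm a [confusion()] matrix (or bare K x K matrix).
#' @return an object of class `eval_report`: list with `per_class` (data
#'   frame: class, sensitivity, specificity, precision, f_measure,
#'   accuracy, undefined), `overall_accuracy`, `macro_sensitivity`,
#'   `macro_specificity`, `macro_f_measure`, `confusion`.
#' @export
metrics_from_confusion <- function(cm) {
  cm <- unclass(as.matrix(cm))
  total <- sum(cm)
  fail_if(total == 0, "confusion matrix is empty")
  K <- nrow(cm)
  class_names <- rownames(cm)
  if (is.null(class_names)) class_names <- as.character(seq_len(K) - 1L)
  ratio <- function(num, den) if (den == 0) 0 else num / den
  per <- lapply(seq_len(K), function(c_) {
    TP <- cm[c_, c_]
    FN <- sum(cm[c_, ]) - TP
    FP <- sum(cm[, c_]) - TP
    TN <- total - TP - FN - FP
    sens <- ratio(TP, TP + FN)
    spec <- ratio(TN, TN + FP)
    prec <- ratio(TP, TP + FP)
    f <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
    data.frame(class = class_names[c_], sensitivity = sens,
               specificity = spec, precision = prec, f_measure = f,
               accuracy = (TP + TN) / total,
               undefined = (TP + FN == 0) || (TP + FP == 0),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  structure(list(per_class = per,
                 overall_accuracy = sum(diag(cm)) / total,
                 macro_sensitivity = mean(per$sensitivity),
                 macro_specificity = mean(per$specificity),
                 macro_f_measure = mean(per$f_measure),
                 confusion = cm),
            class = "eval_report")
}

#' Evaluate a fitted classifier on a held-out feature matrix
#'
#' Predicts, builds the confusion matrix and derives the report.
#'
#' @param model a fitted `bpnn` (or any object with a `predict` method
#'   returning 0-based codes).
#' @param test a `feature_matrix`.
#' @return an `eval_report` (see [metrics_from_confusion()]).
#' @export
evaluate_model <- function(model, test) {
  stopifnot(inherits(test, "feature_matrix"))
  pred <- predict(model, test)
  cm <- confusion(test$labels, pred, length(test$class_names),
                  test$class_names)
  metrics_from_confusion(cm)
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  cat("Evaluation report\n")
  cat(sprintf("  overall accuracy   %.*f\n", digits, x$overall_accuracy))
  cat(sprintf("  macro sensitivity  %.*f\n", digits, x$macro_sensitivity))
  cat(sprintf("  macro specificity  %.*f\n", digits, x$macro_specificity))
  cat(sprintf("  macro F-measure    %.*f\n", digits, x$macro_f_measure))
  cat("Per class:\n")
  pc <- x$per_class
  pc[-1] <- lapply(pc[-1], function(v)
    if (is.numeric(v)) round(v, digits) else v)
  print(pc, row.names = FALSE)
  invisible(x)
}

#' @export
summary.eval_report <- function(object, ...) {
  print(object, ...)
  cat("Confusion matrix (rows = true, columns = predicted):\n")
  print(object$confusion)
  invisible(object)
}

#' Persist an evaluation report
#'
#' Writes the report as JSON (machine-readable) and the confusion matrix
#' as a delimited table with class-name headers.
#'
#' @param report an `eval_report`.
#' @param stem path stem; `<stem>.report.json` and `<stem>.confusion.tsv`
#'   are produced.
#' @return `stem`, invisibly.
#' @export
write_eval_report <- function(report, stem) {
  stopifnot(inherits(report, "eval_report"))
  payload <- list(overall_accuracy = report$overall_accuracy,
                  macro_sensitivity = report$macro_sensitivity,
                  macro_specificity = report$macro_specificity,
                  macro_f_measure = report$macro_f_measure,
                  per_class = report$per_class)
  jsonlite::write_json(payload, paste0(stem, ".report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  utils::write.table(report$confusion, paste0(stem, ".confusion.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  invisible(stem)
}
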