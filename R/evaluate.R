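# Model evaluation: accuracy, macro-averaged precision/recall/F1, the
# confusion matrix and a ranked misclassification list.

#' Evaluate a trained model on a test set
#'
#' Predictions are the arg-max of the model's class-probability output.
#' Accuracy is correct/total; precision, recall and F1 are macro-averaged
#' over the classes present in the test set (the evaluation sets built by
#' this package are class-balanced, so macro and weighted averages agree
#' up to rounding). A class never predicted has precision 0 by convention.
#'
#' @param model An `hsf_cnn` or `hsf_baseline` (anything with a `predict`
#'   method returning a probability matrix with class columns).
#' @param test An `hsf_library` or `list(X, y)`.
#' @return Object of class `hsf_report`: list with `accuracy`,
#'   `macro_precision`, `macro_recall`, `macro_f1` (all percentages),
#'   `confusion` (true x predicted counts) and `misclassifications`
#'   (data.frame true, predicted, count, ranked by count).
#' @export
evaluate <- function(model, test) {
  if (is_library(test))
    test <- library_features(test)
  y <- as.character(test$y)
  if (!length(y)) stop("empty test set")
  p <- stats::predict(model, test$X)
  unknown <- setdiff(unique(y), colnames(p))
  if (length(unknown))
    stop("test set contains class(es) unknown to the model: ",
         paste(unknown, collapse = ", "))
  pred <- colnames(p)[max.col(p, ties.method = "first")]
  metrics_from_predictions(y, pred, colnames(p))
}

# Core metric computation, shared with the hand-built-confusion oracle tests.
metrics_from_predictions <- function(truth, pred, all_classes = NULL) {
  classes <- if (is.null(all_classes)) sort(unique(c(truth, pred)))
    else all_classes
  truth_f <- factor(truth, levels = classes)
  pred_f <- factor(pred, levels = classes)
  confusion <- table(true = truth_f, predicted = pred_f)
  metrics_from_confusion(confusion)
}

#' Compute the report metrics from a confusion matrix
#'
#' @param confusion A square true x predicted count matrix (rows = truth).
#' @return An `hsf_report`.
#' @export
metrics_from_confusion <- function(confusion) {
  confusion <- as.table(confusion)
  names(dimnames(confusion)) <- c("true", "predicted")
  total <- sum(confusion)
  acc <- sum(diag(confusion)) / total
  present <- rownames(confusion)[rowSums(confusion) > 0]
  prec <- rec <- f1 <- numeric(length(present))
  for (i in seq_along(present)) {
    cl <- present[i]
    tp <- confusion[cl, cl]
    fp <- sum(confusion[, cl]) - tp
    fn <- sum(confusion[cl, ]) - tp
    prec[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[i] <- tp / (tp + fn)
    f1[i] <- if (prec[i] + rec[i] > 0)
      2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
  }
  mis <- as.data.frame(confusion, stringsAsFactors = FALSE)
  mis <- mis[mis$true != mis$predicted & mis$Freq > 0, ]
  mis <- mis[order(-mis$Freq), ]
  names(mis) <- c("true", "predicted", "count")
  rownames(mis) <- NULL
  structure(list(accuracy = 100 * acc,
                 macro_precision = 100 * mean(prec),
                 macro_recall = 100 * mean(rec),
                 macro_f1 = 100 * mean(f1),
                 confusion = confusion,
                 misclassifications = mis,
                 n_test = total),
            class = "hsf_report")
}

#' @export
print.hsf_report <- function(x, ...) {
  cat(sprintf(paste0("<hsf_report> n=%d  accuracy %.1f%%  precision %.1f%%",
                     "  recall %.1f%%  F1 %.1f%%\n"),
              x$n_test, x$accuracy, x$macro_precision, x$macro_recall,
              x$macro_f1))
  if (nrow(x$misclassifications)) {
    cat("top misclassifications:\n")
    print(utils::head(x$misclassifications, 5L))
  }
  invisible(x)
}
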