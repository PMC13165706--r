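# Performance metrics -------------------------------------------------------

#' Regression metrics
#'
#' `R2 = 1 - SSE/SST` (SST about the mean of `y_true`), root mean square
#' error and mean absolute error.
#'
#' @param y_true,y_pred numeric vectors of equal length >= 2.
#' @return named list `r2`, `rmse`, `mae`.
#' @export
regression_metrics <- function(y_true, y_pred) {
  assert_that(length(y_true) == length(y_pred) && length(y_true) >= 2,
              "y_true and y_pred must have equal length >= 2")
  sst <- sum((y_true - mean(y_true))^2)
  assert_that(sst > 0, "y_true has zero variance; R2 undefined")
  err <- y_true - y_pred
  list(r2 = 1 - sum(err^2) / sst,
       rmse = sqrt(mean(err^2)),
       mae = mean(abs(err)))
}

#' Build a confusion matrix
#'
#' Rows are true classes, columns predicted classes, over a fixed class
#' set.
#'
#' @param y_true,y_pred label vectors.
#' @param classes class set; defaults to the union of observed labels.
#' @return object of class `confusion_matrix` (integer C x C matrix).
#' @export
confusion_matrix <- function(y_true, y_pred,
                             classes = sort(union(unique(as.character(y_true)),
                                                  unique(as.character(y_pred))))) {
  assert_that(length(y_true) == length(y_pred),
              "y_true and y_pred must have equal length")
  tab <- table(factor(as.character(y_true), levels = classes),
               factor(as.character(y_pred), levels = classes))
  structure(matrix(as.integer(tab), length(classes), length(classes),
                   dimnames = list(true = classes, predicted = classes)),
            class = c("confusion_matrix", "matrix"))
}

#' Classification metrics from a confusion matrix
#'
#' Overall accuracy (`trace / total`); balanced accuracy (arithmetic mean
#' of class-wise recall); macro-averaged F1 from one-vs-rest precision and
#' recall, with an undefined class F1 set to 0 (reported via a message);
#' and the Matthews correlation coefficient in its multiclass
#' correlation-coefficient form, which reduces exactly to the familiar
#' two-class `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#'
#' @param cm a [confusion_matrix()] (any square count matrix accepted).
#' @return named list `accuracy`, `ba`, `f1_macro`, `mcc`.
#' @export
classification_metrics <- function(cm) {
  cm <- unclass(as.matrix(cm))
  assert_that(nrow(cm) == ncol(cm), "confusion matrix must be square")
  total <- sum(cm)
  assert_that(total >= 1, "empty confusion matrix")
  C <- nrow(cm)
  tp <- diag(cm)
  row_sums <- rowSums(cm)   # true-class totals (tp + fn)
  col_sums <- colSums(cm)   # predicted totals  (tp + fp)

  accuracy <- sum(tp) / total
  recall <- ifelse(row_sums > 0, tp / row_sums, 0)
  ba <- mean(recall[row_sums > 0])   # classes absent from truth do not vote
  precision <- ifelse(col_sums > 0, tp / col_sums, 0)
  f1 <- numeric(C)
  for (i in seq_len(C)) {
    denom <- precision[i] + recall[i]
    if (denom == 0) {
      message(sprintf("classification_metrics: F1 undefined for class '%s'; set to 0",
                      rownames(cm)[i] %||% as.character(i)))
      f1[i] <- 0
    } else {
      f1[i] <- 2 * precision[i] * recall[i] / denom
    }
  }
  f1_macro <- mean(f1)

  # multiclass MCC (correlation-coefficient / R_k form)
  num <- sum(tp) * total - sum(row_sums * col_sums)
  den <- sqrt(total^2 - sum(col_sums^2)) * sqrt(total^2 - sum(row_sums^2))
  mcc <- if (den == 0) 0 else num / den

  list(accuracy = accuracy, ba = ba, f1_macro = f1_macro, mcc = mcc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
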