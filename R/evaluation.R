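#' Four-class confusion matrix
#'
#' Counts with rows indexing the true class and columns the predicted
#' class, in the fixed order NH, IC, PH, DH.
#'
#' @param actual,predicted Integer labels 1-4 of equal length.
#' @return 4x4 integer matrix with dimnames `true` x `predicted`.
#' @export
confusion_matrix <- function(actual, predicted) {
  actual <- validate_labels(actual)
  predicted <- validate_labels(predicted)
  if (length(actual) != length(predicted))
    abort("actual and predicted must have equal length")
  m <- table(factor(actual, 1:4), factor(predicted, 1:4))
  m <- matrix(as.integer(m), 4L, 4L,
              dimnames = list(true = names(HUB_CLASSES),
                              predicted = names(HUB_CLASSES)))
  m
}

#' Average correct classification rate
#'
#' The unweighted mean of the four per-class recalls (the diagonal of the
#' row-normalised confusion matrix), as a percentage. Because it depends
#' only on the row-normalised matrix, it is invariant to per-class sample
#' size, which matters for strongly unbalanced hub data. The input may be
#' a raw count matrix or an already row-normalised percentage matrix.
#'
#' @param cm Numeric 4x4 confusion matrix (rows = true class).
#' @return Average CCR in percent.
#' @export
#' @examples
#' cm <- diag(c(90.8, 55.4, 79.7, 82.1))
#' cm[1, 2] <- 9.2; cm[2, 1] <- 44.6; cm[3, 4] <- 20.3; cm[4, 3] <- 17.9
#' average_ccr(cm)
average_ccr <- function(cm) {
  cm <- as.matrix(cm)
  if (!all(dim(cm) == c(4L, 4L))) abort("confusion matrix must be 4x4")
  rs <- rowSums(cm)
  if (any(rs <= 0)) abort("every true class must have samples")
  recalls <- diag(cm) / rs
  mean(recalls) * 100
}

#' Correlation of actual and predicted labels
#'
#' Pearson correlation of the integer label codings (1 = NH ... 4 = DH),
#' as a percentage. A single global score that rewards getting the ordered
#' role scale right, complementing the per-class rates.
#'
#' @inheritParams confusion_matrix
#' @return Correlation in percent (range -100..100).
#' @export
label_correlation <- function(actual, predicted) {
  actual <- validate_labels(actual)
  predicted <- validate_labels(predicted)
  if (length(actual) != length(predicted))
    abort("actual and predicted must have equal length")
  if (sd(actual) == 0 || sd(predicted) == 0)
    abort("label correlation undefined for a constant label vector")
  cor(actual, predicted) * 100
}

#' One-vs-rest classification metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, positive predictive
#' value `TP/(TP+FP)` and negative predictive value `TN/(TN+FN)` for each
#' class against the rest, plus the merged PH+DH super-class (any-hub
#' detection). Percentages; a zero denominator yields `NA`.
#'
#' @param cm Numeric 4x4 confusion matrix (rows = true class); fractional
#'   counts are accepted, e.g. when reconstructing counts from printed
#'   percentages.
#' @return Tibble with columns `class`, `sensitivity`, `specificity`,
#'   `ppv`, `npv` (5 rows: NH, IC, PH, DH, PH+DH).
#' @export
ovr_metrics <- function(cm) {
  cm <- as.matrix(cm)
  if (!all(dim(cm) == c(4L, 4L))) abort("confusion matrix must be 4x4")
  total <- sum(cm)
  if (total <= 0) abort("empty confusion matrix")
  one <- function(rows, cols) {
    tp <- sum(cm[rows, cols, drop = FALSE])
    fn <- sum(cm[rows, , drop = FALSE]) - tp
    fp <- sum(cm[, cols, drop = FALSE]) - tp
    tn <- total - tp - fn - fp
    ratio <- function(a, b) if (a + b > 0) 100 * a / (a + b) else NA_real_
    c(sensitivity = ratio(tp, fn), specificity = ratio(tn, fp),
      ppv = ratio(tp, fp), npv = ratio(tn, fn))
  }
  res <- rbind(one(1, 1), one(2, 2), one(3, 3), one(4, 4), one(3:4, 3:4))
  tibble::tibble(class = c(names(HUB_CLASSES), "PH+DH"),
                 sensitivity = res[, "sensitivity"],
                 specificity = res[, "specificity"],
                 ppv = res[, "ppv"], npv = res[, "npv"])
}

#' Area under the ROC curve
#'
#' One-vs-rest AROC for a class score, computed by the midrank
#' (Mann-Whitney) formulation, which equals the trapezoidal area over all
#' thresholds with ties given half credit.
#'
#' @param actual Integer labels 1-4 (or a logical vector of positives).
#' @param scores Numeric per-sample score for the positive class (e.g. its
#'   posterior probability).
#' @param positive_class Which label counts as positive when `actual` is
#'   not logical; may be a vector of labels (e.g. `c(3, 4)` for any-hub).
#' @return AROC in `[0, 1]`.
#' @export
roc_auc <- function(actual, scores, positive_class = NULL) {
  if (is.logical(actual)) {
    pos <- actual
  } else {
    if (is.null(positive_class))
      abort("positive_class is required for integer labels")
    pos <- actual %in% positive_class
  }
  if (length(pos) != length(scores))
    abort("actual and scores must have equal length")
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    abort("both classes must be present to compute an AROC")
  r <- rank(scores)                       # midranks handle ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full evaluation report
#'
#' Bundles every evaluation statistic the package reports for one set of
#' predictions: the confusion matrix, average CCR, label correlation,
#' one-vs-rest metrics, and (when posteriors are supplied) the per-class
#' one-vs-rest AROC.
#'
#' @inheritParams confusion_matrix
#' @param posteriors Optional matrix (samples x 4) of class posteriors for
#'   the AROC curves.
#' @return An object of class `evaluation_report`.
#' @export
evaluate_predictions <- function(actual, predicted, posteriors = NULL) {
  cm <- confusion_matrix(actual, predicted)
  auc <- NULL
  if (!is.null(posteriors)) {
    auc <- vapply(1:4, function(c)
      tryCatch(roc_auc(actual, posteriors[, c], positive_class = c),
               error = function(e) NA_real_), 0)
    names(auc) <- names(HUB_CLASSES)
  }
  structure(list(confusion = cm,
                 average_ccr = average_ccr(cm),
                 correlation = tryCatch(label_correlation(actual, predicted),
                                        error = function(e) NA_real_),
                 ovr = ovr_metrics(cm),
                 auc = auc,
                 n = length(actual)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> n =", x$n, "\n")
  cat(sprintf("  average CCR %.1f%%  label correlation %.1f%%\n",
              x$average_ccr, x$correlation))
  pct <- round(100 * x$confusion / rowSums(x$confusion), 1)
  print(pct)
  if (!is.null(x$auc))
    cat("  AROC:", paste(names(x$auc), sprintf("%.3f", x$auc),
                         collapse = "  "), "\n")
  invisible(x)
}
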