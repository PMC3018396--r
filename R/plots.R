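#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' ROC curve points
#'
#' Computes the one-vs-rest ROC curve (false and true positive rates over
#' all score thresholds) for one class.
#'
#' @inheritParams roc_auc
#' @return Tibble with columns `fpr`, `tpr`, ordered along the curve.
#' @export
roc_points <- function(actual, scores, positive_class = NULL) {
  pos <- if (is.logical(actual)) actual else actual %in% positive_class
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
  # collapse score ties to one point
  keep <- c(diff(scores[ord]) != 0, TRUE)
  tibble::tibble(fpr = c(0, fp[keep] / sum(!pos)),
                 tpr = c(0, tp[keep] / sum(pos)))
}

#' Plot an evaluation report
#'
#' Heat map of the row-normalised confusion matrix (per-class recall on
#' the diagonal).
#'
#' @param object An `evaluation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evaluation_report <- function(object, ...) {
  pct <- 100 * object$confusion / rowSums(object$confusion)
  d <- tibble::as_tibble(as.table(pct), .name_repair = "minimal")
  names(d) <- c("true", "predicted", "percent")
  ggplot2::ggplot(d, ggplot2::aes(.data$predicted,
                                  factor(.data$true,
                                         rev(names(HUB_CLASSES))),
                                  fill = .data$percent)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f", .data$percent)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 100)) +
    ggplot2::labs(x = "predicted class", y = "true class",
                  fill = "% of row") +
    ggplot2::theme_minimal()
}

#' Plot experiment ROC curves
#'
#' One-vs-rest ROC curve per class from the experiment's test-set
#' posteriors, annotated with the AROC values.
#'
#' @param object A `hub_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hub_experiment <- function(object, ...) {
  p <- object$predictions
  curves <- dplyr::bind_rows(lapply(1:4, function(c)
    dplyr::mutate(roc_points(p$actual, p[[names(HUB_CLASSES)[c]]],
                             positive_class = c),
                  class = names(HUB_CLASSES)[c])))
  auc <- object$report$auc
  lab <- if (!is.null(auc))
    paste0(names(auc), " (AROC ", sprintf("%.2f", auc), ")") else NULL
  if (!is.null(lab))
    curves$class <- factor(curves$class, names(HUB_CLASSES), lab)
  ggplot2::ggplot(curves, ggplot2::aes(.data$fpr, .data$tpr,
                                       colour = .data$class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a fusion trace
#'
#' Cross-validated average CCR of every fusion trial, accepted steps
#' highlighted.
#'
#' @param object A `fusion_result` (see [greedy_forward_fusion()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fusion_result <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(.data$step, .data$cv_ccr,
                               colour = .data$accepted)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(data = object$trace[object$trace$accepted, ],
                       colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "steelblue",
                                            `FALSE` = "grey60")) +
    ggplot2::labs(x = "trial", y = "CV average CCR (%)",
                  colour = "accepted") +
    ggplot2::theme_minimal()
}
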