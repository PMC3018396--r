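#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy evaluation results
#'
#' `tidy()` on an evaluation report returns the one-vs-rest metric table
#' (one row per class, plus the merged PH+DH super-class), with the
#' per-class AROC joined in when posteriors were available. `glance()`
#' returns the one-row summary: average CCR, label correlation and sample
#' count.
#'
#' @param x An `evaluation_report` (see [evaluate_predictions()]).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.evaluation_report <- function(x, ...) {
  out <- x$ovr
  if (!is.null(x$auc))
    out <- dplyr::left_join(
      out, tibble::tibble(class = names(x$auc), auc = unname(x$auc)),
      by = "class")
  out
}

#' @rdname tidy.evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) {
  tibble::tibble(average_ccr = x$average_ccr, correlation = x$correlation,
                 n = x$n)
}

#' Tidy a fitted experiment
#'
#' `tidy()` returns the per-class test metrics; `glance()` the one-row
#' experiment summary including the fused feature sets.
#'
#' @param x A `hub_experiment` (see [run_experiment()]).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.hub_experiment <- function(x, ...) tidy(x$report)

#' @rdname tidy.hub_experiment
#' @export
glance.hub_experiment <- function(x, ...) {
  dplyr::bind_cols(glance(x$report),
                   tibble::tibble(
                     n_sets = length(x$selected_sets),
                     sets = paste(x$selected_sets, collapse = "+"),
                     classifier = x$config$classifier$method,
                     min_risk = !is.null(x$config$classifier$cost_matrix)))
}

#' Tidy a supervised PCA fit
#'
#' `tidy()` returns the loadings in long form (one row per kept feature
#' and component) together with each feature's screening F score;
#' `glance()` summarises the reduction.
#'
#' @param x A `supervised_pca` fit.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.supervised_pca <- function(x, ...) {
  feats <- if (!is.null(x$feature_names)) x$feature_names[x$selected]
           else paste0("V", x$selected)
  tibble::tibble(feature = rep(feats, ncol(x$loadings)),
                 component = rep(colnames(x$loadings), each = nrow(x$loadings)),
                 loading = as.vector(x$loadings),
                 f_score = rep(unname(x$f_scores[x$selected]),
                               ncol(x$loadings)))
}

#' @rdname tidy.supervised_pca
#' @export
glance.supervised_pca <- function(x, ...) {
  tibble::tibble(n_features = x$n_features,
                 n_selected = length(x$selected),
                 n_components = ncol(x$loadings),
                 sdev1 = x$sdev[1])
}

#' Tidy Bayes classifier fits
#'
#' One row per class with the prior and, for the mixture model, the chosen
#' component count and final log-likelihood.
#'
#' @param x A `gaussian_bayes` or `mdm_bayes` fit.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.gaussian_bayes <- function(x, ...) {
  tibble::tibble(class = names(HUB_CLASSES),
                 prior = vapply(x$classes, `[[`, 0, "prior"))
}

#' @rdname tidy.gaussian_bayes
#' @export
tidy.mdm_bayes <- function(x, ...) {
  tibble::tibble(class = names(HUB_CLASSES),
                 prior = vapply(x$classes, `[[`, 0, "prior"),
                 components = vapply(x$classes, `[[`, 0L, "m"),
                 loglik = vapply(x$classes, `[[`, 0, "loglik"),
                 em_iterations = vapply(x$classes, `[[`, 0L, "iterations"))
}
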