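#' Stratified train/test split
#'
#' Samples each class separately and without replacement so the train set
#' holds `round(train_fraction * class size)` members of every class.
#' Deterministic given the seed.
#'
#' @param labels Tibble with columns `protein_id` and `label`, or an
#'   integer label vector (ids then default to the positions).
#' @param train_fraction Fraction of each class assigned to training.
#' @param seed Integer seed.
#' @return List with character/integer vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_fraction = 0.7, seed = 1L) {
  lt <- as_label_table(labels)
  if (train_fraction <= 0 || train_fraction >= 1)
    abort("train_fraction must be in (0, 1)")
  if (any(table(factor(lt$label, 1:4)) < 2L))
    abort("every class needs at least 2 members to split")
  with_seed(seed, {
    train <- unlist(lapply(split(lt$protein_id, lt$label), function(ids) {
      n_tr <- round(train_fraction * length(ids))
      sample(ids, n_tr)
    }), use.names = FALSE)
    list(train = train, test = setdiff(lt$protein_id, train))
  })
}

as_label_table <- function(labels) {
  if (is.data.frame(labels)) {
    stopifnot(all(c("protein_id", "label") %in% names(labels)))
    tibble::tibble(protein_id = labels$protein_id,
                   label = validate_labels(labels$label))
  } else {
    tibble::tibble(protein_id = seq_along(labels),
                   label = validate_labels(labels))
  }
}

#' Stratified k-fold cross-validation folds
#'
#' Partitions the ids into `folds` stratified folds; each id validates
#' exactly once and per-fold class proportions track the global ones.
#'
#' @param ids Vector of sample ids.
#' @param labels Integer labels 1-4 aligned with `ids`.
#' @param folds Number of folds (default 5).
#' @param seed Integer seed.
#' @return List of `folds` elements, each `list(fit = ids, validate =
#'   ids)`.
#' @export
kfold_cv <- function(ids, labels, folds = 5L, seed = 1L) {
  labels <- validate_labels(labels)
  if (length(ids) != length(labels)) abort("ids and labels differ in length")
  if (folds < 2L) abort("folds must be >= 2")
  if (folds > min(table(factor(labels, 1:4))[table(factor(labels, 1:4)) > 0]))
    abort("folds exceeds the smallest class size")
  with_seed(seed, {
    fold_of <- integer(length(ids))
    for (c in unique(labels)) {
      pos <- which(labels == c)
      fold_of[pos] <- sample(rep_len(seq_len(folds), length(pos)))
    }
    lapply(seq_len(folds), function(f)
      list(fit = ids[fold_of != f], validate = ids[fold_of == f]))
  })
}

#' Classifier specification
#'
#' A light container naming the classifier and its hyperparameters, used
#' by the fusion search and [run_experiment()].
#'
#' @param method One of `"gauss"`, `"mdm"`, `"knn"`.
#' @param k KNN neighbourhood size.
#' @param max_components MDM per-class mixture-size cap.
#' @param cost_matrix Optional 4x4 cost matrix; when present predictions
#'   use [min_risk_decide()] instead of [decide_map()].
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(method = c("gauss", "mdm", "knn"), k = 5L,
                            max_components = 3L, cost_matrix = NULL) {
  method <- match.arg(method)
  if (!is.null(cost_matrix)) validate_cost_matrix(cost_matrix)
  structure(list(method = method, k = k, max_components = max_components,
                 cost_matrix = cost_matrix), class = "classifier_spec")
}

train_classifier <- function(X, y, spec, seed = 1L) {
  switch(spec$method,
         gauss = fit_gaussian_bayes(X, y),
         mdm = fit_mdm_bayes(X, y, max_components = spec$max_components,
                             seed = seed),
         knn = fit_knn(X, y, k = min(spec$k, nrow(X))))
}

predict_classifier <- function(model, X, spec) {
  post <- class_posteriors(model, X)
  labels <- if (is.null(spec$cost_matrix)) decide_map(post)
            else min_risk_decide(post, spec$cost_matrix)
  list(labels = labels, posteriors = post)
}

# pooled cross-validated average CCR and label correlation for one
# feature matrix
cv_metrics <- function(X, labels, spec, folds = 5L, seed = 1L) {
  ids <- seq_len(nrow(X))
  plan <- kfold_cv(ids, labels, folds, seed)
  pred <- integer(length(ids))
  for (f in plan) {
    model <- train_classifier(X[f$fit, , drop = FALSE], labels[f$fit],
                              spec, seed)
    pred[f$validate] <-
      predict_classifier(model, X[f$validate, , drop = FALSE], spec)$labels
  }
  list(ccr = average_ccr(confusion_matrix(labels, pred)),
       corr = tryCatch(label_correlation(labels, pred),
                       error = function(e) NA_real_))
}

#' Greedy forward fusion of feature sets
#'
#' Implements the forward feature-set selection used to combine
#' encodings: sets are first ranked by their standalone cross-validated
#' average CCR; the best set seeds the fusion, and candidates are then
#' tried in rank order, each kept only if concatenating it strictly
#' improves *both* the cross-validated average CCR and the label
#' correlation of the current combination. The search stops when no
#' remaining candidate improves the combination. Every trial is recorded
#' in the trace.
#'
#' @param reduced A `feature_collection` of already-reduced sets (e.g.
#'   from [reduce_collection()]), all rows training samples.
#' @param labels Integer labels aligned with the rows.
#' @param spec A [classifier_spec()].
#' @param folds,seed Cross-validation folds and seed.
#' @return List with `selected` (character vector of set names, in
#'   acceptance order) and `trace` (tibble: step, candidate, sets tried,
#'   CV average CCR, CV correlation, accepted flag).
#' @export
greedy_forward_fusion <- function(reduced, labels, spec, folds = 5L,
                                  seed = 1L) {
  if (length(reduced) == 0L) abort("empty feature collection")
  labels <- validate_labels(labels)
  standalone <- vapply(reduced, function(X)
    cv_metrics(X, labels, spec, folds, seed)$ccr, 0)
  rank_order <- names(sort(standalone, decreasing = TRUE))

  selected <- rank_order[1L]
  current <- cv_metrics(reduced[[selected]], labels, spec, folds, seed)
  trace <- tibble::tibble(step = 1L, candidate = selected,
                          sets = selected, cv_ccr = current$ccr,
                          cv_corr = current$corr, accepted = TRUE)
  step <- 1L
  remaining <- setdiff(rank_order, selected)
  repeat {
    accepted_any <- FALSE
    for (cand in remaining) {
      step <- step + 1L
      trial_sets <- c(selected, cand)
      Xf <- do.call(cbind, reduced[trial_sets])
      m <- cv_metrics(Xf, labels, spec, folds, seed)
      ok <- isTRUE(m$ccr > current$ccr) && isTRUE(m$corr > current$corr)
      trace <- dplyr::bind_rows(trace, tibble::tibble(
        step = step, candidate = cand,
        sets = paste(trial_sets, collapse = "+"),
        cv_ccr = m$ccr, cv_corr = m$corr, accepted = ok))
      if (ok) {
        selected <- trial_sets
        current <- m
        remaining <- setdiff(remaining, cand)
        accepted_any <- TRUE
        break
      }
    }
    if (!accepted_any || length(remaining) == 0L) break
  }
  structure(list(selected = selected, trace = trace),
            class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat("<fusion_result>", paste(x$selected, collapse = " + "), "\n")
  cat("  ", sum(x$trace$accepted), "accepted of", nrow(x$trace),
      "trials\n")
  invisible(x)
}

#' Experiment configuration
#'
#' Collects every knob of a full classification experiment. Defaults
#' follow the package's standard protocol: a stratified 70/30 train/test
#' split, 5-fold cross-validation inside the training set, three combined
#' features per encoding, and minimum-risk decisions under the
#' hub-prioritising cost matrix.
#'
#' @param seed Master seed; all randomness in the experiment derives from
#'   it.
#' @param sets Feature encodings to extract (see [feature_set_names()]).
#' @param train_fraction Train share of each class.
#' @param folds Cross-validation folds.
#' @param n_components,screen_fraction Reduction settings (see
#'   [fit_supervised_pca()]).
#' @param classifier A [classifier_spec()].
#' @param fuse If `TRUE` run the greedy forward fusion; otherwise all
#'   extracted sets are concatenated.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(seed = 1L,
                              sets = c("aac", "pairs_1gap", "domains",
                                       "go_cc_1", "disorder", "pssm400"),
                              train_fraction = 0.7, folds = 5L,
                              n_components = 3L, screen_fraction = 0.5,
                              classifier = classifier_spec(
                                "gauss", cost_matrix = hub_cost_matrix()),
                              fuse = TRUE) {
  if (train_fraction <= 0 || train_fraction >= 1)
    abort("train_fraction must be in (0, 1)")
  if (folds < 2L) abort("folds must be >= 2")
  structure(list(seed = as.integer(seed), sets = sets,
                 train_fraction = train_fraction, folds = folds,
                 n_components = n_components,
                 screen_fraction = screen_fraction,
                 classifier = classifier, fuse = fuse),
            class = "experiment_config")
}

#' Run a full classification experiment
#'
#' Executes the end-to-end protocol on a dataset: extract the configured
#' feature encodings, split stratified 70/30, reduce each encoding with
#' supervised PCA fitted on the training rows only, optionally run the
#' greedy forward fusion (cross-validated within the training set, so the
#' test set never influences model or set selection), train the final
#' classifier on the fused training features, predict the held-out test
#' set, and evaluate. Deterministic given `config$seed`.
#'
#' @param dataset A [hub_dataset].
#' @param config An [experiment_config()].
#' @param out_dir Optional directory; when given, predictions (TSV) and
#'   the evaluation report (JSON) are written there.
#' @return An object of class `hub_experiment`: list with `report`
#'   (an `evaluation_report` on the test set), `fusion` (selected sets +
#'   trace, or NULL), `predictions` (tibble), `split`, `reduction` and
#'   `model`.
#' @export
run_experiment <- function(dataset, config = experiment_config(),
                           out_dir = NULL) {
  stopifnot(inherits(dataset, "hub_dataset"),
            inherits(config, "experiment_config"))
  collection <- extract_features(dataset, config$sets)
  lt <- dataset$labels
  split <- stratified_split(lt, config$train_fraction, config$seed)
  ids <- dataset$proteins$id
  tr_idx <- match(split$train, ids)
  te_idx <- match(split$test, ids)
  y <- lt$label

  red <- reduce_collection(collection, y, train_idx = tr_idx,
                           n_components = config$n_components,
                           screen_fraction = config$screen_fraction)
  train_sets <- lapply(red$reduced, function(X) X[tr_idx, , drop = FALSE])
  train_sets <- structure(train_sets, class = "feature_collection")

  fusion <- NULL
  if (isTRUE(config$fuse) && length(collection) > 1L) {
    fusion <- greedy_forward_fusion(train_sets, y[tr_idx],
                                    config$classifier, config$folds,
                                    config$seed)
    sel <- fusion$selected
  } else {
    sel <- names(collection)
  }

  X_train <- do.call(cbind, lapply(red$reduced[sel],
                                   function(X) X[tr_idx, , drop = FALSE]))
  X_test <- do.call(cbind, lapply(red$reduced[sel],
                                  function(X) X[te_idx, , drop = FALSE]))
  model <- train_classifier(X_train, y[tr_idx], config$classifier,
                            config$seed)
  pred <- predict_classifier(model, X_test, config$classifier)
  report <- evaluate_predictions(y[te_idx], pred$labels, pred$posteriors)

  predictions <- tibble::tibble(protein_id = split$test,
                                actual = y[te_idx],
                                predicted = pred$labels) |>
    dplyr::bind_cols(tibble::as_tibble(pred$posteriors))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(predictions, file.path(out_dir, "predictions.tsv"))
    jsonlite::write_json(
      list(average_ccr = report$average_ccr,
           correlation = report$correlation,
           confusion = report$confusion, ovr = report$ovr,
           auc = report$auc, selected_sets = sel),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }

  structure(list(report = report, fusion = fusion,
                 predictions = predictions, split = split,
                 reduction = red$models, model = model,
                 selected_sets = sel, config = config),
            class = "hub_experiment")
}

#' @export
print.hub_experiment <- function(x, ...) {
  cat("<hub_experiment>", x$config$classifier$method,
      if (is.null(x$config$classifier$cost_matrix)) "(MAP)"
      else "(min-risk)", "\n")
  cat("  sets:", paste(x$selected_sets, collapse = " + "), "\n")
  cat(sprintf("  test average CCR %.1f%%, correlation %.1f%%\n",
              x$report$average_ccr, x$report$correlation))
  invisible(x)
}
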