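#' Gaussian Bayes classifier
#'
#' Fits a four-class Bayes classifier with one multivariate normal
#' class-conditional density per class: priors are the training class
#' frequencies, and each class's mean and covariance are maximum-likelihood
#' estimates from its training rows. A small ridge (by default `1e-6` times
#' the mean covariance diagonal) keeps every covariance positive definite;
#' when a class has fewer samples than `dimension + 1` the ridge is raised
#' and a warning emitted.
#'
#' @param X Numeric training matrix (samples x features).
#' @param y Integer labels 1-4; every class must be present.
#' @param ridge Optional ridge added to covariance diagonals; default
#'   `1e-6 * mean(diag(cov))` per class.
#' @return An object of class `gaussian_bayes`.
#' @export
fit_gaussian_bayes <- function(X, y, ridge = NULL) {
  X <- as.matrix(X)
  y <- validate_labels(y)
  if (length(y) != nrow(X)) abort("X rows and y length differ")
  if (!all(1:4 %in% y)) abort("every class 1..4 must appear in y")
  d <- ncol(X)
  classes <- lapply(1:4, function(c) {
    rows <- X[y == c, , drop = FALSE]
    n <- nrow(rows)
    mu <- colMeans(rows)
    S <- crossprod(sweep(rows, 2, mu)) / n          # ML covariance
    lam <- ridge %||% (1e-6 * max(mean(diag(S)), 1e-8))
    if (n < d + 1L) {
      lam <- max(lam, 1e-2 * max(mean(diag(S)), 1))
      warn(paste0("class ", c, " has ", n, " samples for ", d,
                  " dimensions; covariance ridge raised"))
    }
    list(prior = n / nrow(X), mean = mu,
         cov = ridge_spd(S, lam), ridge = lam)
  })
  structure(list(classes = classes, d = d), class = "gaussian_bayes")
}

# add ridge until Cholesky succeeds
ridge_spd <- function(S, lam) {
  for (i in 0:10) {
    Sr <- S + diag(lam * 10^i, nrow(S))
    ok <- tryCatch({ chol(Sr); TRUE }, error = function(e) FALSE)
    if (ok) return(Sr)
  }
  abort("covariance could not be regularised")
}

# rowwise log N(x; mu, S) via Cholesky
log_mvnorm <- function(X, mu, S) {
  R <- chol(S)
  Z <- forwardsolve(t(R), t(sweep(X, 2, mu)))
  -0.5 * colSums(Z^2) - sum(log(diag(R))) - 0.5 * ncol(X) * log(2 * pi)
}

#' @export
print.gaussian_bayes <- function(x, ...) {
  cat("<gaussian_bayes>", x$d, "dims; priors",
      paste(sprintf("%.3f", vapply(x$classes, `[[`, 0, "prior")),
            collapse = " "), "\n")
  invisible(x)
}

#' K-nearest-neighbour classifier
#'
#' Stores the training rows and predicts by majority vote among the `k`
#' Euclidean-nearest neighbours. All ties are deterministic: equal
#' distances rank by training-row order, and vote ties resolve to the
#' lowest class index.
#'
#' @inheritParams fit_gaussian_bayes
#' @param k Neighbourhood size, `1 <= k <= nrow(X)`.
#' @return An object of class `knn_model`.
#' @export
fit_knn <- function(X, y, k = 5L) {
  X <- as.matrix(X)
  y <- validate_labels(y)
  if (nrow(X) == 0L) abort("empty training set")
  if (k < 1L || k > nrow(X)) abort("k must be in 1..nrow(X)")
  structure(list(X = X, y = y, k = as.integer(k), d = ncol(X)),
            class = "knn_model")
}

#' @rdname fit_knn
#' @param X_train,y_train,X_test Training features/labels and query rows.
#' @return `fit_predict_knn()`: integer vector of predicted labels.
#' @export
fit_predict_knn <- function(X_train, y_train, X_test, k) {
  model <- fit_knn(X_train, y_train, k)
  decide_map(class_posteriors(model, X_test))
}

#' Class posterior probabilities
#'
#' For the Bayes models, `P(class | x)` proportional to prior times the
#' class-conditional density, computed in the log domain (so extreme
#' points underflow to a well-defined posterior instead of NaN). For a KNN
#' model, the vote fractions among the `k` nearest neighbours.
#'
#' @param model A `gaussian_bayes`, `mdm_bayes` or `knn_model` fit.
#' @param X Numeric matrix of query rows (a single vector is accepted).
#' @return Numeric matrix (rows x 4) of posteriors, rows summing to 1,
#'   columns named NH, IC, PH, DH.
#' @export
class_posteriors <- function(model, X) {
  UseMethod("class_posteriors")
}

as_query_matrix <- function(X, d) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  if (ncol(X) != d)
    abort(paste0("expected ", d, "-dimensional input, got ", ncol(X)))
  X
}

finish_posteriors <- function(logp) {
  m <- apply(logp, 1, max)
  p <- exp(logp - m)
  p <- p / rowSums(p)
  colnames(p) <- names(HUB_CLASSES)
  p
}

#' @export
class_posteriors.gaussian_bayes <- function(model, X) {
  X <- as_query_matrix(X, model$d)
  logp <- vapply(model$classes, function(cl)
    log(cl$prior) + log_mvnorm(X, cl$mean, cl$cov), numeric(nrow(X)))
  if (nrow(X) == 1L) logp <- matrix(logp, nrow = 1L)
  finish_posteriors(logp)
}

#' @export
class_posteriors.knn_model <- function(model, X) {
  X <- as_query_matrix(X, model$d)
  tr <- model$X
  # squared Euclidean distances, queries x training rows
  d2 <- outer(rowSums(X^2), rep(1, nrow(tr))) - 2 * X %*% t(tr) +
    outer(rep(1, nrow(X)), rowSums(tr^2))
  p <- t(apply(d2, 1, function(row) {
    nn <- order(row)[seq_len(model$k)]      # stable: index breaks dist ties
    tabulate(model$y[nn], nbins = 4L) / model$k
  }))
  colnames(p) <- names(HUB_CLASSES)
  p
}

#' Decision rules
#'
#' `decide_map()` returns the maximum-posterior class; `min_risk_decide()`
#' returns the class minimising the expected cost
#' `risk(j) = sum_i L[i, j] * P(i | x)` under a cost matrix `L` (rows =
#' true class, columns = predicted class). With the zero-one loss
#' `1 - diag(4)` the two rules coincide. All ties break toward the lowest
#' class index.
#'
#' @param posteriors Probability 4-vector or matrix (rows x 4).
#' @param L 4x4 cost matrix, e.g. [hub_cost_matrix()].
#' @return Integer labels (1-4), one per posterior row.
#' @export
#' @examples
#' decide_map(c(0.7, 0.1, 0.1, 0.1))
#' min_risk_decide(c(0.6, 0.2, 0.1, 0.1), hub_cost_matrix())
decide_map <- function(posteriors) {
  P <- if (is.null(dim(posteriors))) matrix(posteriors, nrow = 1L)
       else as.matrix(posteriors)
  as.integer(apply(P, 1, which.max))        # which.max: lowest-index ties
}

#' @rdname decide_map
#' @export
min_risk_decide <- function(posteriors, L) {
  validate_cost_matrix(L)
  P <- if (is.null(dim(posteriors))) matrix(posteriors, nrow = 1L)
       else as.matrix(posteriors)
  risks <- P %*% L
  as.integer(apply(risks, 1, which.min))    # which.min: lowest-index ties
}
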