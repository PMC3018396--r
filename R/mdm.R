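#' Mixture-density Bayes classifier
#'
#' Bayes classifier whose class-conditional densities are Gaussian mixture
#' models fitted by expectation-maximisation, for classes whose feature
#' distribution is multimodal or otherwise non-Gaussian. Per class, EM is
#' run for every component count `m = 1..max_components` (k-means++
#' initialisation, full covariances with a stabilising ridge) and the
#' per-class `m` is chosen by cross-validated held-out log-likelihood; the
#' chosen mixture is then refitted on all of the class's training rows.
#' With `max_components = 1` the model reduces exactly to
#' [fit_gaussian_bayes()].
#'
#' @inheritParams fit_gaussian_bayes
#' @param max_components Largest mixture size considered per class.
#' @param tol EM convergence tolerance on the relative log-likelihood
#'   change.
#' @param max_iter Maximum EM iterations.
#' @param seed Integer seed driving initialisation and fold assignment.
#' @param cv_folds Folds for the component-count selection.
#' @return An object of class `mdm_bayes`; each class entry records the
#'   mixture weights, means, covariances, chosen `m`, final
#'   log-likelihood, iteration count and the log-likelihood trace.
#' @export
fit_mdm_bayes <- function(X, y, max_components = 3L, tol = 1e-6,
                          max_iter = 500L, seed = 1L, cv_folds = 5L) {
  X <- as.matrix(X)
  y <- validate_labels(y)
  if (!all(1:4 %in% y)) abort("every class 1..4 must appear in y")
  if (max_components < 1L) abort("max_components must be >= 1")
  d <- ncol(X)
  classes <- vector("list", 4L)
  for (c in 1:4) {
    rows <- X[y == c, , drop = FALSE]
    m <- with_seed(seed + c, select_components(rows, max_components, tol,
                                               max_iter, cv_folds))
    fit <- with_seed(seed * 131L + c,
                     fit_gmm(rows, m, tol, max_iter))
    fit$prior <- nrow(rows) / nrow(X)
    classes[[c]] <- fit
  }
  structure(list(classes = classes, d = d, seed = seed), class = "mdm_bayes")
}

#' @export
print.mdm_bayes <- function(x, ...) {
  cat("<mdm_bayes>", x$d, "dims; components per class:",
      paste(vapply(x$classes, `[[`, 0L, "m"), collapse = " "), "\n")
  invisible(x)
}

#' @export
class_posteriors.mdm_bayes <- function(model, X) {
  X <- as_query_matrix(X, model$d)
  logp <- vapply(model$classes, function(cl)
    log(cl$prior) + log_gmm_density(X, cl), numeric(nrow(X)))
  if (nrow(X) == 1L) logp <- matrix(logp, nrow = 1L)
  finish_posteriors(logp)
}

# rowwise mixture log-density
log_gmm_density <- function(X, gmm) {
  comp <- vapply(seq_len(gmm$m), function(k)
    log(gmm$weights[k]) + log_mvnorm(X, gmm$means[k, ], gmm$covs[[k]]),
    numeric(nrow(X)))
  if (nrow(X) == 1L) comp <- matrix(comp, nrow = 1L)
  row_logsumexp(comp)
}

row_logsumexp <- function(M) {
  m <- apply(M, 1, max)
  m + log(rowSums(exp(M - m)))
}

# pick component count by cv_folds-fold held-out log-likelihood per
# observation; small classes fall back to fewer folds / m = 1
select_components <- function(rows, max_components, tol, max_iter,
                              cv_folds) {
  n <- nrow(rows); d <- ncol(rows)
  m_cap <- min(max_components, max(1L, floor(n / (d + 2L))))
  if (m_cap == 1L || n < 2L * cv_folds) return(1L)
  folds <- sample(rep_len(seq_len(cv_folds), n))
  scores <- vapply(seq_len(m_cap), function(m) {
    ll <- 0; nobs <- 0
    for (f in seq_len(cv_folds)) {
      tr <- rows[folds != f, , drop = FALSE]
      te <- rows[folds == f, , drop = FALSE]
      fit <- tryCatch(fit_gmm(tr, m, tol, max_iter),
                      error = function(e) NULL)
      if (is.null(fit)) return(-Inf)
      ll <- ll + sum(log_gmm_density(te, fit))
      nobs <- nobs + nrow(te)
    }
    ll / nobs
  }, 0)
  which.max(scores)          # ties -> smaller m
}

# EM fit of an m-component full-covariance Gaussian mixture
fit_gmm <- function(rows, m, tol = 1e-6, max_iter = 500L) {
  n <- nrow(rows); d <- ncol(rows)
  if (n == 0L) abort("cannot fit a mixture to an empty class")
  if (m == 1L) {
    mu <- colMeans(rows)
    S <- crossprod(sweep(rows, 2, mu)) / n
    lam <- 1e-6 * max(mean(diag(S)), 1e-8)
    fit <- list(m = 1L, weights = 1, means = matrix(mu, 1L),
                covs = list(ridge_spd(S, lam)))
    fit$loglik <- sum(log_gmm_density(rows, fit))
    fit$trace <- fit$loglik
    fit$iterations <- 0L
    return(fit)
  }
  centers <- kmeanspp_centers(rows, m)
  assign <- apply(sq_dist(rows, centers), 1, which.min)
  gmm <- m_step(rows, hard_resp(assign, m, n))
  trace <- numeric()
  ll_prev <- -Inf
  for (it in seq_len(max_iter)) {
    comp <- vapply(seq_len(gmm$m), function(k)
      log(gmm$weights[k]) + log_mvnorm(rows, gmm$means[k, ], gmm$covs[[k]]),
      numeric(n))
    if (n == 1L) comp <- matrix(comp, nrow = 1L)
    lse <- row_logsumexp(comp)
    ll <- sum(lse)
    trace <- c(trace, ll)
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) <= tol * (abs(ll_prev) + 1e-12)) break
    ll_prev <- ll
    resp <- exp(comp - lse)
    # prune collapsed components
    w <- colSums(resp) / n
    keep <- w > 1e-8
    if (!all(keep)) {
      warn("pruning collapsed mixture component(s)")
      comp <- comp[, keep, drop = FALSE]
      lse <- row_logsumexp(comp)
      resp <- exp(comp - lse)
      gmm$m <- sum(keep)
    }
    gmm <- m_step(rows, resp)
  }
  gmm$loglik <- trace[length(trace)]
  gmm$trace <- trace
  gmm$iterations <- length(trace)
  gmm
}

hard_resp <- function(assign, m, n) {
  R <- matrix(0, n, m)
  R[cbind(seq_len(n), assign)] <- 1
  # empty cluster: seed it with its nearest orphan weighting
  empty <- which(colSums(R) == 0)
  for (k in empty) R[sample.int(n, 1L), k] <- 1
  R
}

m_step <- function(rows, resp) {
  n <- nrow(rows); m <- ncol(resp)
  nk <- colSums(resp)
  weights <- nk / n
  means <- do.call(rbind, lapply(seq_len(m), function(k)
    colSums(rows * resp[, k]) / nk[k]))
  covs <- lapply(seq_len(m), function(k) {
    Z <- sweep(rows, 2, means[k, ])
    S <- crossprod(Z * sqrt(resp[, k])) / nk[k]
    ridge_spd(S, 1e-6 * max(mean(diag(S)), 1e-8))
  })
  list(m = m, weights = weights, means = means, covs = covs)
}

kmeanspp_centers <- function(rows, m) {
  n <- nrow(rows)
  idx <- sample.int(n, 1L)
  for (k in seq_len(m - 1L)) {
    d2 <- apply(sq_dist(rows, rows[idx, , drop = FALSE]), 1, min)
    d2[idx] <- 0
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx <- c(idx, sample.int(n, 1L, prob = p))
  }
  rows[idx, , drop = FALSE]
}

sq_dist <- function(A, B) {
  outer(rowSums(A^2), rep(1, nrow(B))) - 2 * A %*% t(B) +
    outer(rep(1, nrow(A)), rowSums(B^2))
}

# evaluate code under a temporary RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
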