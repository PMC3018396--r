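#' Supervised principal-component reduction of a feature set
#'
#' Reduces one feature encoding to a handful of combined features (three by
#' default) by label-informed screening followed by PCA: features are
#' ranked by their one-way ANOVA F statistic across the four classes, the
#' top `screen_fraction` retained (never fewer than `n_components`),
#' standardised to zero mean / unit variance (constant features dropped),
#' and projected onto the leading principal components of the screened
#' block. With `screen_fraction = 1` this degrades gracefully to ordinary
#' (unsupervised) PCA on standardised features.
#'
#' The fit is deterministic: features are ranked with stable ties, and each
#' component's sign is fixed so its largest-magnitude loading is positive.
#'
#' @param X Numeric matrix (proteins x features).
#' @param y Integer class labels (1-4), one per row of `X`.
#' @param n_components Number of combined output features (default 3).
#' @param screen_fraction Fraction of features kept after F screening,
#'   in (0, 1].
#' @return An object of class `supervised_pca` with elements `selected`
#'   (kept column indices), `center`, `scale`, `loadings`
#'   (kept-features x components), `f_scores`, and `sdev`.
#' @seealso [predict.supervised_pca()]
#' @export
fit_supervised_pca <- function(X, y, n_components = 3L,
                               screen_fraction = 0.5) {
  X <- as.matrix(X)
  y <- validate_labels(y)
  if (length(y) != nrow(X)) abort("X rows and y length differ")
  if (length(unique(y)) < 2L)
    abort("supervised PCA needs at least 2 classes")
  if (screen_fraction <= 0 || screen_fraction > 1)
    abort("screen_fraction must be in (0, 1]")

  f <- anova_f_scores(X, y)
  n_keep <- max(ceiling(screen_fraction * ncol(X)), n_components)
  keep <- order(f, decreasing = TRUE)[seq_len(min(n_keep, ncol(X)))]
  keep <- sort(keep)                       # stable original order

  ctr <- colMeans(X[, keep, drop = FALSE])
  scl <- apply(X[, keep, drop = FALSE], 2, sd)
  nonconst <- scl > 0
  keep <- keep[nonconst]
  if (length(keep) < n_components)
    abort("fewer informative features than requested components")
  ctr <- ctr[nonconst]; scl <- scl[nonconst]

  Z <- scale(X[, keep, drop = FALSE], center = ctr, scale = scl)
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  W <- pc$rotation[, seq_len(n_components), drop = FALSE]
  # fix component signs: largest-magnitude loading positive
  for (j in seq_len(ncol(W))) {
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  colnames(W) <- paste0("PC", seq_len(ncol(W)))
  structure(list(selected = keep, center = ctr, scale = scl, loadings = W,
                 f_scores = f, sdev = pc$sdev[seq_len(n_components)],
                 n_features = ncol(X),
                 feature_names = colnames(X)),
            class = "supervised_pca")
}

# vectorised one-way ANOVA F statistic per feature column
anova_f_scores <- function(X, y) {
  g <- factor(y)
  n <- nrow(X); G <- nlevels(g)
  grand <- colMeans(X)
  ssb <- rep(0, ncol(X)); ssw <- rep(0, ncol(X))
  for (lev in levels(g)) {
    rows <- which(g == lev)
    mg <- colMeans(X[rows, , drop = FALSE])
    ssb <- ssb + length(rows) * (mg - grand)^2
    ssw <- ssw + colSums((X[rows, , drop = FALSE] -
                            rep(mg, each = length(rows)))^2)
  }
  f <- (ssb / (G - 1)) / (ssw / (n - G))
  f[ssw == 0 & ssb > 0] <- Inf           # perfect separators
  f[ssw == 0 & ssb == 0] <- -Inf         # constants rank last
  f
}

#' Project data through a fitted reduction
#'
#' @param object A fitted [fit_supervised_pca()] model.
#' @param newdata Numeric matrix with the model's original feature count.
#' @param ... Unused.
#' @return Numeric matrix (rows x components), row names preserved.
#' @export
predict.supervised_pca <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features)
    abort(paste0("expected ", object$n_features, " features, got ",
                 ncol(newdata)))
  Z <- scale(newdata[, object$selected, drop = FALSE],
             center = object$center, scale = object$scale)
  out <- Z %*% object$loadings
  rownames(out) <- rownames(newdata)
  out
}

#' @export
print.supervised_pca <- function(x, ...) {
  cat("<supervised_pca>", length(x$selected), "of", x$n_features,
      "features ->", ncol(x$loadings), "components\n")
  invisible(x)
}

#' Reduce every set of a feature collection
#'
#' Fits one supervised PCA per feature set on the training rows and
#' projects all rows, yielding the reduced collection the classifiers and
#' the fusion search consume.
#'
#' @param collection A `feature_collection` (see [extract_features()]).
#' @param y Labels aligned with the collection rows.
#' @param train_idx Integer row indices used for fitting (all rows by
#'   default); other rows are only projected.
#' @inheritParams fit_supervised_pca
#' @return List with `reduced` (feature_collection of projected matrices)
#'   and `models` (named list of `supervised_pca` fits).
#' @export
reduce_collection <- function(collection, y, train_idx = NULL,
                              n_components = 3L, screen_fraction = 0.5) {
  if (is.null(train_idx)) train_idx <- seq_along(y)
  models <- lapply(collection, function(X)
    fit_supervised_pca(X[train_idx, , drop = FALSE], y[train_idx],
                       n_components, screen_fraction))
  reduced <- lapply(names(collection), function(nm) {
    m <- predict(models[[nm]], collection[[nm]])
    colnames(m) <- paste0(nm, "_", colnames(m))
    m
  })
  names(reduced) <- names(collection)
  list(reduced = structure(reduced, class = "feature_collection"),
       models = models)
}
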