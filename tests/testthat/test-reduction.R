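make_screening_data <- function(n_per_class = 40, n_noise = 50,
                                effect = 2) {
  y <- rep(1:4, each = n_per_class)
  n <- length(y)
  X_inf <- sapply(1:3, function(j)
    rnorm(n, mean = effect * as.numeric(y == j)))
  X <- cbind(X_inf, matrix(rnorm(n * n_noise), n))
  colnames(X) <- c(paste0("inf", 1:3), paste0("noise", seq_len(n_noise)))
  list(X = X, y = y)
}

test_that("screening retains class-informative features", {
  set.seed(21)
  d <- make_screening_data()
  fit <- fit_supervised_pca(d$X, d$y, screen_fraction = 0.2)
  expect_true(all(1:3 %in% fit$selected))
  expect_equal(ncol(fit$loadings), 3L)
  expect_equal(ncol(predict(fit, d$X)), 3L)
})

test_that("screening F statistic matches stats::oneway.test", {
  set.seed(22)
  d <- make_screening_data(n_per_class = 15, n_noise = 5)
  fit <- fit_supervised_pca(d$X, d$y, screen_fraction = 1)
  for (j in c(1, 4, 7)) {
    ref <- stats::oneway.test(d$X[, j] ~ factor(d$y),
                              var.equal = TRUE)$statistic
    expect_equal(unname(fit$f_scores[j]), unname(ref), tolerance = 1e-10)
  }
})

test_that("loadings are orthogonal with variance-ordered components", {
  set.seed(23)
  d <- make_screening_data()
  fit <- fit_supervised_pca(d$X, d$y)
  G <- crossprod(fit$loadings)
  expect_equal(G, diag(3), tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(fit$sdev) <= 1e-12))
  # sign convention: largest-magnitude loading positive
  for (j in 1:3)
    expect_gt(fit$loadings[which.max(abs(fit$loadings[, j])), j], 0)
})

test_that("transform centres training data and is linear over rows", {
  set.seed(24)
  d <- make_screening_data()
  fit <- fit_supervised_pca(d$X, d$y)
  Z <- predict(fit, d$X)
  expect_equal(unname(colMeans(Z)), rep(0, 3), tolerance = 1e-8)

  # duplicated row -> duplicated transformed row
  X2 <- rbind(d$X, d$X[1, , drop = FALSE])
  Z2 <- predict(fit, X2)
  expect_equal(unname(Z2[nrow(X2), ]), unname(Z2[1, ]))

  # batch transform equals per-row transforms
  rows <- lapply(1:5, function(i) predict(fit, d$X[i, , drop = FALSE]))
  expect_equal(unname(do.call(rbind, rows)), unname(Z[1:5, ]))

  expect_error(predict(fit, d$X[, 1:10]), "expected")
})

test_that("refitting on identical data is deterministic", {
  set.seed(25)
  d <- make_screening_data()
  f1 <- fit_supervised_pca(d$X, d$y)
  f2 <- fit_supervised_pca(d$X, d$y)
  expect_identical(f1$loadings, f2$loadings)
  expect_identical(f1$selected, f2$selected)
})

test_that("PCA on orthonormal columns preserves distances up to rotation", {
  set.seed(26)
  Q <- qr.Q(qr(matrix(rnorm(40 * 3), 40, 3)))
  y <- rep(1:4, each = 10)
  fit <- fit_supervised_pca(Q, y, screen_fraction = 1)
  Z <- predict(fit, Q)
  expect_equal(as.matrix(dist(scale(Q))), as.matrix(dist(Z)),
               tolerance = 1e-8)
})

test_that("degenerate inputs are rejected", {
  X <- matrix(rnorm(40), 20, 2)
  expect_error(fit_supervised_pca(X, rep(1, 20)), "2 classes")
  Xc <- matrix(1, 20, 4)
  expect_error(fit_supervised_pca(Xc, rep(1:2, 10)), "informative")
})

test_that("reduce_collection reduces every set to three columns", {
  set.seed(27)
  d <- make_screening_data()
  coll <- structure(list(a = d$X, b = d$X[, 1:10]),
                    class = "feature_collection")
  red <- reduce_collection(coll, d$y, train_idx = 1:120)
  expect_equal(vapply(red$reduced, ncol, 0L), c(a = 3L, b = 3L))
  expect_equal(nrow(red$reduced$a), nrow(d$X))
})
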