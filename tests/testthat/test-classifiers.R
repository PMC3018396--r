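# 1-D four-class training data; classes 3 and 4 placed far away so the
# first two behave as an isolated two-class problem where needed
make_1d_data <- function(n, means = c(0, 10, 100, 110), sds = rep(1, 4)) {
  y <- rep(1:4, each = n)
  X <- matrix(rnorm(length(y), mean = means[y], sd = sds[y]), ncol = 1)
  list(X = X, y = y)
}

test_that("equal-variance Gaussian classes split at the midpoint", {
  set.seed(31)
  d <- make_1d_data(2000)
  fit <- fit_gaussian_bayes(d$X, d$y)
  grid <- matrix(seq(2, 8, by = 0.001), ncol = 1)
  pred <- decide_map(class_posteriors(fit, grid))
  boundary <- grid[max(which(pred == 1)), 1]
  expect_lt(abs(boundary - 5), 0.2)
})

test_that("single-sample classes fit with a raised ridge", {
  X <- matrix(c(0, 1, 2, 3), ncol = 1)
  w <- capture_warnings(fit <- fit_gaussian_bayes(X, 1:4))
  expect_match(w, "ridge", all = TRUE)
  expect_equal(vapply(fit$classes, `[[`, 0, "prior"), rep(0.25, 4))
  p <- class_posteriors(fit, matrix(1.2))
  expect_equal(sum(p), 1)
})

test_that("posteriors are normalised, symmetric and underflow-safe", {
  set.seed(32)
  d <- make_1d_data(200)
  fit <- fit_gaussian_bayes(d$X, d$y)
  P <- class_posteriors(fit, d$X)
  expect_equal(unname(rowSums(P)), rep(1, nrow(P)))
  # extreme query: log-domain computation keeps the argmax defined
  Pe <- class_posteriors(fit, matrix(1e6))
  expect_false(anyNA(Pe))
  expect_equal(decide_map(Pe), 4L)
})

test_that("MAP decisions match a brute-force prior-density rule", {
  set.seed(33)
  d <- make_1d_data(500)
  fit <- fit_gaussian_bayes(d$X, d$y)
  # independent oracle: sample moments + dnorm on a dense grid
  mu <- vapply(1:4, function(c) mean(d$X[d$y == c, ]), 0)
  s <- vapply(1:4, function(c) {
    x <- d$X[d$y == c, ]; sqrt(mean((x - mean(x))^2))
  }, 0)
  prior <- as.vector(table(d$y)) / length(d$y)
  grid <- seq(-5, 115, length.out = 1000)
  oracle <- vapply(grid, function(x)
    which.max(log(prior) + dnorm(x, mu, s, log = TRUE)), 0L)
  pred <- decide_map(class_posteriors(fit, matrix(grid, ncol = 1)))
  expect_gte(mean(pred == oracle), 0.999)
})

test_that("MAP tie-breaks go to the lowest class index", {
  expect_equal(decide_map(c(0.7, 0.1, 0.1, 0.1)), 1L)
  expect_equal(decide_map(c(0.25, 0.25, 0.25, 0.25)), 1L)
  expect_equal(decide_map(c(0.1, 0.2, 0.3, 0.4)), 4L)
})

test_that("minimum-risk with zero-one loss reduces to MAP", {
  set.seed(34)
  L01 <- matrix(1, 4, 4) - diag(4)
  P <- matrix(rexp(4e4), ncol = 4)
  P <- P / rowSums(P)
  expect_equal(min_risk_decide(P, L01), decide_map(P))
})

test_that("the hub cost matrix shifts decisions toward hub classes", {
  L <- hub_cost_matrix()
  # risks (0.20, 0.24, 0.18, 0.18): PH wins on the tie-break
  expect_equal(min_risk_decide(c(0.6, 0.2, 0.1, 0.1), L), 3L)
  # uniform posterior: risks (0.475, 0.475, 0.15, 0.15)
  expect_equal(min_risk_decide(rep(0.25, 4), L), 3L)

  set.seed(35)
  P <- matrix(rexp(4e4), ncol = 4)
  P <- P / rowSums(P)
  map <- decide_map(P)
  mr <- min_risk_decide(P, L)
  expect_lte(sum(mr %in% 1:2), sum(map %in% 1:2))
})

test_that("KNN votes deterministically with documented tie rules", {
  X <- matrix(c(0, 1, 2, 10, 11, 12), ncol = 1)
  y <- c(2, 2, 4, 3, 4, 1)
  # k = 1 on a training point returns its own label
  expect_equal(fit_predict_knn(X, y, X, k = 1), y)
  # k = 3 around x = 1: neighbours labelled 2,2,4 -> 2
  expect_equal(fit_predict_knn(X, y, matrix(1), k = 3), 2L)
  # vote tie (3,4) -> lowest class index 3
  expect_equal(fit_predict_knn(X, y, matrix(10.5), k = 2), 3L)
  # distance tie: lower training-row index is the nearer neighbour
  Xt <- matrix(c(0, 2), ncol = 1); yt <- c(4L, 1L)
  expect_equal(fit_predict_knn(Xt, yt, matrix(1), k = 1), 4L)
  expect_error(fit_knn(X, y, k = 10), "k must be")
})

test_that("KNN posteriors are vote fractions", {
  X <- matrix(c(0, 0.5, 1, 50), ncol = 1)
  y <- c(1, 1, 2, 3)
  m <- fit_knn(X, y, k = 3)
  p <- class_posteriors(m, matrix(0.4))
  expect_equal(unname(p[1, ]), c(2 / 3, 1 / 3, 0, 0))
})
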