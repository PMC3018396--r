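test_that("confusion matrix accumulates counts in fixed class order", {
  a <- c(1, 1, 2, 3, 4); p <- c(1, 4, 2, 3, 4)
  cm <- confusion_matrix(a, p)
  expect_equal(sum(cm), 5)
  expect_equal(cm["NH", "DH"], 1L)
  expect_equal(diag(cm), setNames(c(1L, 1L, 1L, 1L), names(HUB_CLASSES)))
  # permutation of samples leaves counts unchanged
  o <- c(3, 1, 5, 2, 4)
  expect_equal(confusion_matrix(a[o], p[o]), cm)
  expect_error(confusion_matrix(1:3, 1:2), "equal length")
})

test_that("average CCR is the mean per-class recall in percent", {
  cm <- diag(c(10, 20, 30, 40))
  expect_equal(average_ccr(cm), 100)
  cm2 <- rbind(c(8, 2, 0, 0), c(1, 3, 0, 0), c(0, 0, 5, 5),
               c(0, 0, 0, 10))
  expect_equal(average_ccr(cm2), mean(c(0.8, 0.75, 0.5, 1)) * 100)
  # rebalancing rows leaves the statistic unchanged
  expect_equal(average_ccr(cm2 * c(10, 1, 3, 7)), average_ccr(cm2))
  cm2[2, ] <- 0
  expect_error(average_ccr(cm2), "every true class")
})

test_that("label correlation is Pearson on the 1-4 coding, in percent", {
  a <- c(1, 2, 3, 4, 1, 2, 3, 4)
  expect_equal(label_correlation(a, a), 100)
  expect_equal(label_correlation(a, 5 - a), -100)
  set.seed(51)
  x <- sample(1:4, 10000, replace = TRUE)
  y <- sample(1:4, 10000, replace = TRUE)
  expect_lt(abs(label_correlation(x, y)), 5)
  expect_error(label_correlation(rep(1, 5), c(1, 2, 1, 2, 1)), "constant")
})

test_that("one-vs-rest metrics satisfy the count identity", {
  set.seed(52)
  cm <- matrix(rpois(16, 20), 4, 4)
  m <- ovr_metrics(cm)
  expect_equal(m$class, c("NH", "IC", "PH", "DH", "PH+DH"))
  # per class TP+FN+FP+TN = total, so sens/spec weighted counts recombine
  for (c in 1:4) {
    tp <- cm[c, c]; fn <- sum(cm[c, ]) - tp; fp <- sum(cm[, c]) - tp
    tn <- sum(cm) - tp - fn - fp
    expect_equal(tp + fn + fp + tn, sum(cm))
    expect_equal(m$sensitivity[c], 100 * tp / (tp + fn))
    expect_equal(m$specificity[c], 100 * tn / (tn + fp))
  }
  perfect <- diag(c(5, 5, 5, 5))
  mp <- ovr_metrics(perfect)
  expect_true(all(as.matrix(mp[, -1]) == 100))
})

test_that("AROC matches the pair-ordering oracle and its extremes", {
  pos <- c(rep(TRUE, 5), rep(FALSE, 5))
  s <- c(6:10, 1:5)
  expect_equal(roc_auc(pos, s), 1)
  expect_equal(roc_auc(pos, -s), 0)

  set.seed(53)
  for (i in 1:10) {
    n <- sample(20:200, 1)
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(pos) || all(pos)) next
    sc <- sample(1:20, n, replace = TRUE)  # heavy ties
    expect_equal(roc_auc(pos, sc), naive_auc(pos, sc))
  }

  # independent scores: null AUC near 1/2
  pos <- sample(c(TRUE, FALSE), 10000, replace = TRUE)
  expect_lt(abs(roc_auc(pos, rnorm(10000)) - 0.5), 0.02)
  expect_error(roc_auc(rep(TRUE, 5), 1:5), "both classes")
})

test_that("AROC agrees with pROC on integer labels", {
  skip_if_not_installed("pROC")
  set.seed(54)
  y <- sample(1:4, 300, replace = TRUE)
  sc <- rnorm(300) + (y == 3)
  ref <- as.numeric(pROC::auc(pROC::roc(y == 3, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(y, sc, positive_class = 3), ref, tolerance = 1e-12)
})

test_that("evaluation reports bundle all statistics coherently", {
  set.seed(55)
  a <- sample(1:4, 400, replace = TRUE)
  post <- matrix(rexp(1600), ncol = 4)
  post <- post / rowSums(post)
  p <- decide_map(post)
  rep <- evaluate_predictions(a, p, post)
  expect_equal(rep$average_ccr, average_ccr(confusion_matrix(a, p)))
  expect_equal(nrow(tidy(rep)), 5L)
  expect_named(glance(rep), c("average_ccr", "correlation", "n"))
  expect_length(rep$auc, 4L)
})
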