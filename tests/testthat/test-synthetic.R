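test_that("degree sampling follows a reproducible truncated power law", {
  d <- generate_degrees(10000, 2.5, seed = 3)
  expect_identical(generate_degrees(10000, 2.5, seed = 3), d)
  expect_true(all(d >= 1))
  # hub-degree tail mass is plausible for a protein interaction network
  expect_gt(mean(d >= 9), 0.01)
  expect_lt(mean(d >= 9), 0.20)
  # exact truncated discrete maximum-likelihood exponent
  nll <- function(g) g * sum(log(d)) + length(d) * log(sum((1:500)^(-g)))
  g_hat <- optimize(nll, c(1.1, 5))$minimum
  expect_lt(abs(g_hat - 2.5), 0.3)
  expect_error(generate_degrees(5, 2.5), "at least 10")
  expect_error(generate_degrees(100, 0.9), "exceed 1")
})

test_that("role assignment implements the degree and co-expression rules", {
  cfg <- synthetic_config()
  expect_equal(assign_roles(1L, 0.9, cfg), 1L)
  expect_equal(assign_roles(5L, 0.9, cfg), 2L)
  expect_equal(assign_roles(10L, 0.8, cfg), 3L)
  expect_equal(assign_roles(10L, 0.1, cfg), 4L)
  # boundary degrees: 2 -> NH, 3 and 8 -> IC, 9 -> hub
  expect_equal(assign_roles(c(2L, 3L, 8L, 9L), rep(0.9, 4), cfg),
               c(1L, 2L, 2L, 3L))
  # pure function of its inputs
  set.seed(61)
  deg <- sample(1:30, 500, replace = TRUE)
  pcc <- runif(500, -1, 1)
  expect_identical(assign_roles(deg, pcc, cfg),
                   assign_roles(deg, pcc, cfg))
})

test_that("simulated metadata is label-consistent and seed-stable", {
  cfg <- synthetic_config(n = 300, with_pssm = FALSE)
  ds <- simulate_proteins(cfg, seed = 7)
  expect_identical(assign_roles(ds$meta$degree, ds$meta$avg_pcc, cfg),
                   ds$labels$label)
  ds2 <- simulate_proteins(cfg, seed = 8)
  expect_false(identical(ds$proteins$sequence, ds2$proteins$sequence))
  expect_identical(names(ds2), names(ds))
})

test_that("the class mix tracks the configured proportions", {
  ds <- simulate_proteins(synthetic_config(n = 1000, with_pssm = FALSE),
                          seed = 12)
  nh <- sum(ds$labels$label == 1L)
  # multinomial: 3 sd around 814
  expect_lt(abs(nh - 814), 3 * sqrt(1000 * 0.814 * 0.186))
})

test_that("null effects make the class compositions indistinguishable", {
  ds <- simulate_proteins(synthetic_config(n = 2000, effect = 0,
                                           mix = rep(0.25, 4),
                                           with_pssm = FALSE), seed = 13)
  A <- extract_features(ds, "aac")$aac
  means <- sapply(1:4, function(c)
    colMeans(A[ds$labels$label == c, , drop = FALSE]))
  l1 <- max(unlist(lapply(1:3, function(i) sapply((i + 1):4, function(j)
    sum(abs(means[, i] - means[, j]))))))
  # within sampling noise of identical compositions; strong effects give
  # pairwise L1 distances above 0.5 on the same design
  expect_lt(l1, 0.05)
})

test_that("hubs carry more domains than non-hubs under default effects", {
  ds <- simulate_proteins(synthetic_config(n = 1200, with_pssm = FALSE),
                          seed = 14)
  ndom <- table(factor(ds$annotations$domains$protein_id,
                       ds$proteins$id))
  counts <- as.numeric(ndom)
  hub <- ds$labels$label %in% 3:4
  expect_gt(mean(counts[hub]), mean(counts[!hub]))
})

test_that("written datasets are complete, consistent and reloadable", {
  cfg <- synthetic_config(n = 50, with_pssm = TRUE)
  dir <- withr::local_tempdir()
  ds <- generate_dataset(cfg, dir, seed = 20)
  back <- load_dataset(dir)
  expect_equal(back$proteins, ds$proteins)
  expect_equal(back$labels, ds$labels)
  # every protein has a label and a profile
  expect_setequal(names(back$pssms), back$proteins$id)
  # ASCII profiles round-trip up to integer rounding of the scores
  id <- ds$proteins$id[1]
  expect_equal(back$pssms[[id]]$scores, round(ds$pssms[[id]]$scores),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(back$pssms[[id]]$sequence, ds$pssms[[id]]$sequence)
  # annotations survive the TSV round trip after normalisation
  expect_equal(back$annotations$go, ds$annotations$go)
  d1 <- dplyr::arrange(back$annotations$domains, .data$protein_id,
                       .data$position)
  d2 <- dplyr::arrange(ds$annotations$domains, .data$protein_id,
                       .data$position)
  expect_equal(d1, d2)
})

test_that("generated proteins honour class-conditional construction", {
  set.seed(30)
  cfg <- synthetic_config(n = 100, with_pssm = TRUE)
  rec <- generate_protein(cfg, 4L, id = "x1")
  expect_gte(nchar(rec$sequence), cfg$min_length)
  expect_s3_class(rec$pssm, "pssm_profile")
  expect_equal(nchar(rec$sequence), nrow(rec$pssm$scores))
  expect_error(synthetic_config(effect = -1), "effect")
  expect_error(synthetic_config(hub_threshold = 2, nonhub_threshold = 3),
               "below")
})
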