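test_that("single-residue composition fractions are counts over length", {
  v <- aac("AAAC")
  expect_equal(unname(v[c("A", "C")]), c(0.75, 0.25))
  expect_equal(sum(v), 1)
  expect_equal(unname(aac("M")["M"]), 1)
  expect_error(aac(""), "length")
})

test_that("pair compositions match their printed formulas", {
  expect_equal(unname(dipeptide_comp("AAA")["AA"]), 1)
  v <- dipeptide_comp("ACAC")
  expect_equal(unname(v[c("AC", "CA")]), c(2 / 3, 1 / 3))
  expect_length(v, 400L)

  g <- gapped_pair_comp("ACA", k = 1)
  expect_equal(unname(g["AA"]), 1)
  g2 <- gapped_pair_comp("ACDCA", k = 1)
  expect_equal(unname(g2[c("AD", "CC", "DA")]), rep(1 / 3, 3))
  expect_error(gapped_pair_comp("AC", k = 1), "length")
})

test_that("composition ops agree with a brute-force counter", {
  set.seed(42)
  for (i in 1:100) {
    # occasionally include nonstandard letters
    alpha <- if (i %% 7 == 0) c(AA20, "X", "B") else AA20
    s <- random_sequence(sample(8:50, 1), alpha)
    expect_equal(aac(s), naive_aac(s))
    expect_equal(dipeptide_comp(s), naive_gapped(s, 0))
    k <- sample(1:4, 1)
    if (nchar(s) >= k + 2)
      expect_equal(gapped_pair_comp(s, k), naive_gapped(s, k))
  }
})

test_that("gapped pairs with k = 0 equal dipeptides and normalise", {
  set.seed(7)
  for (i in 1:20) {
    s <- random_sequence(sample(5:60, 1))
    expect_identical(gapped_pair_comp(s, 0), dipeptide_comp(s))
    expect_equal(sum(aac(s)), 1, tolerance = 1e-9)
    expect_equal(sum(dipeptide_comp(s)), 1, tolerance = 1e-9)
    expect_equal(sum(gapped_pair_comp(s, 2)), 1, tolerance = 1e-9)
  }
})

test_that("co-occurrence matrix is the row-major reshape of gapped pairs", {
  M <- cooccurrence_matrix("ACA", k = 1)
  expect_equal(dim(M), c(20L, 20L))
  expect_equal(unname(M["A", "A"]), 1)
  expect_equal(sum(M), 1)

  set.seed(3)
  s <- random_sequence(40)
  M2 <- cooccurrence_matrix(s, k = 2)
  expect_equal(as.vector(t(M2)), unname(gapped_pair_comp(s, 2)))
})

test_that("Haralick statistics handle degenerate matrices", {
  single <- matrix(0, 20, 20); single[1, 1] <- 1
  h <- haralick_features(single)
  expect_equal(unname(h[c("energy", "entropy", "inertia",
                          "inverse_difference_moment")]),
               c(1, 0, 0, 1))
  expect_equal(unname(h["correlation"]), 0)  # zero-variance marginal

  unif <- matrix(1 / 400, 20, 20)
  hu <- haralick_features(unif)
  expect_equal(unname(hu["energy"]), 1 / 400)
  expect_equal(unname(hu["entropy"]), log2(400))

  expect_error(haralick_features(matrix(0, 20, 20)), "sum")
})

test_that("Haralick statistics equal direct summation on random matrices", {
  set.seed(11)
  for (i in 1:5) {
    P <- matrix(0, 20, 20)
    supp <- sample(20, 4)
    P[supp, supp] <- runif(16)
    expect_equal(haralick_features(P), naive_haralick(P),
                 tolerance = 1e-12)
  }
})

test_that("Haralick ranges hold on random protein sequences", {
  set.seed(5)
  for (i in 1:20) {
    h <- haralick_features(cooccurrence_matrix(random_sequence(80), 1))
    expect_gt(h[["energy"]], 0); expect_lte(h[["energy"]], 1)
    expect_gte(h[["entropy"]], 0)
    expect_lte(h[["entropy"]], log2(400))
    expect_gt(h[["inverse_difference_moment"]], 0)
    expect_lte(h[["inverse_difference_moment"]], 1)
  }
})

test_that("physicochemical fractions count group membership", {
  tab <- default_property_table()
  v <- physicochemical_comp("HFWY", tab)
  expect_equal(unname(v["aromatic"]), 1)
  expect_equal(unname(physicochemical_comp("HAAA", tab)["aromatic"]), 0.25)
  # a group with no members present scores zero
  expect_equal(unname(physicochemical_comp("AAAA", tab)["tryptophan"]), 0)
  expect_length(v, 48L)
})

test_that("length feature is the aac denominator", {
  expect_equal(unname(length_feature("ACDE")), 4)
  expect_equal(unname(length_feature("M")), 1)
  s <- random_sequence(33)
  expect_equal(unname(length_feature(s)),
               sum(aac(s)) * nchar(s))  # standard-only: N * 1
})
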