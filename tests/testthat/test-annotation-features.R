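test_that("domain membership encodes presence over the vocabulary", {
  v <- domain_vector(c("d2", "d3"), c("d1", "d2", "d3"))
  expect_equal(unname(v), c(0L, 1L, 1L))
  expect_equal(unname(domain_vector(character(), c("d1", "d2"))), c(0L, 0L))
  expect_error(domain_vector("dX", c("d1")), "not in vocabulary")
  expect_warning(v2 <- domain_vector(c("dX", "d1"), c("d1"),
                                     lenient = TRUE), "dropping")
  expect_equal(unname(v2), 1L)
})

test_that("repeated domains require adjacency in the ordered list", {
  vocab <- c("A", "B")
  expect_equal(unname(repeated_domain_vector(c("A", "A", "B"), vocab)),
               c(1L, 0L))
  expect_equal(unname(repeated_domain_vector(c("A", "B", "A"), vocab)),
               c(0L, 0L))
  expect_equal(unname(repeated_domain_vector(c("A", "A", "A", "B", "B"),
                                             vocab)), c(1L, 1L))
  # families mapping: two adjacent domains of the same family
  fam <- c(d1 = "F1", d2 = "F1", d3 = "F2")
  expect_equal(unname(repeated_domain_vector(c("d1", "d2", "d3"),
                                             c("F1", "F2"),
                                             families = fam)), c(1L, 0L))
})

test_that("repeated-domain flags never exceed family presence", {
  set.seed(8)
  vocab <- LETTERS[1:6]
  for (i in 1:50) {
    doms <- sample(vocab, sample(0:8, 1), replace = TRUE)
    rep_v <- repeated_domain_vector(doms, vocab)
    pres <- domain_vector(unique(doms), vocab)
    expect_true(all(rep_v <= pres))
  }
})

test_that("GO level encoding handles unannotated and unknown terms", {
  vocab <- sprintf("BP1:%02d", 1:19)
  v <- go_level_vector(c("BP1:03", "BP1:11"), vocab)
  expect_equal(sum(v), 2L)
  expect_length(v, 19L)
  expect_equal(sum(go_level_vector(character(), vocab)), 0L)
  expect_warning(go_level_vector("XX:01", vocab), "dropping")
  expect_length(go_level_vector(character(), sprintf("CC1:%02d", 1:8)), 8L)
})

test_that("disorder summaries follow run-length arithmetic", {
  expect_equal(unname(disorder_features(NULL, 100)), rep(0, 4))
  expect_equal(unname(disorder_features(data.frame(start = 10, end = 50),
                                        100)),
               c(0.4, 1, 40, 40))
  expect_equal(unname(disorder_features(
    data.frame(start = c(0, 20), end = c(10, 50)), 100)),
    c(0.4, 2, 30, 20))
  expect_error(disorder_features(data.frame(start = 90, end = 120), 100),
               "outside")
})

test_that("pssm20 averages the percentage block into fractions", {
  unif <- matrix(5, 4, 20)
  prof <- pssm_profile(matrix(0, 4, 20), "ACDE", unif)
  expect_equal(unname(pssm20(prof)), rep(0.05, 20))

  single <- matrix(0, 1, 20); single[1, 1] <- 100
  prof1 <- pssm_profile(matrix(0, 1, 20), "A", single)
  expect_equal(unname(pssm20(prof1)[1]), 1)
  expect_equal(sum(pssm20(prof1)), 1)

  set.seed(4)
  pc <- matrix(runif(60, 0, 100), 3, 20)
  prof2 <- pssm_profile(matrix(0, 3, 20), "MKL", pc)
  expect_equal(unname(pssm20(prof2)), colMeans(pc) / 100)

  # no percentages: softmax fallback, flagged
  prof3 <- pssm_profile(matrix(rnorm(60), 3, 20), "MKL")
  expect_warning(v <- pssm20(prof3), "softmax")
  expect_equal(sum(v), 1, tolerance = 1e-9)
})

test_that("pssm400 averages score rows per residue type then squashes", {
  set.seed(9)
  sc <- matrix(rnorm(40), 2, 20)
  prof <- pssm_profile(sc, "AA")
  v <- pssm400(prof)
  expect_length(v, 400L)
  expect_equal(unname(v[1:20]), plogis(colMeans(sc)))
  # every other residue block is squashed zero = 0.5
  expect_equal(unname(v[21:400]), rep(0.5, 380))
  expect_true(all(v > 0 & v < 1))
})

test_that("pssm400 is invariant to shuffling positions within residue type", {
  set.seed(10)
  s <- random_sequence(60)
  sc <- matrix(rnorm(60 * 20), 60, 20)
  perm <- sample(60)
  ch <- strsplit(s, "")[[1]]
  prof1 <- pssm_profile(sc, s)
  prof2 <- pssm_profile(sc[perm, ], paste(ch[perm], collapse = ""))
  expect_equal(pssm400(prof1), pssm400(prof2))
})
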