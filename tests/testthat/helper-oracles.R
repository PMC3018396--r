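# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately re-derive quantities with naive loops so they share
# no code with the package implementation.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

pair_names20 <- as.vector(t(outer(AA20, AA20, paste0)))

random_sequence <- function(len, alphabet = AA20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# naive single-residue composition
naive_aac <- function(s) {
  ch <- strsplit(s, "")[[1]]
  v <- setNames(numeric(20), AA20)
  for (c in ch) if (c %in% AA20) v[c] <- v[c] + 1
  v / length(ch)
}

# naive gapped-pair composition (k = 0 gives dipeptides)
naive_gapped <- function(s, k) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  v <- setNames(numeric(400), pair_names20)
  for (i in seq_len(n - 1 - k)) {
    a <- ch[i]; b <- ch[i + k + 1]
    if (a %in% AA20 && b %in% AA20)
      v[paste0(a, b)] <- v[paste0(a, b)] + 1
  }
  v / (n - 1 - k)
}

# naive Haralick statistics by direct summation
naive_haralick <- function(P) {
  p <- P / sum(P)
  ng <- nrow(p)
  l2 <- function(x) if (x > 0) log2(x) else 0
  px <- rowSums(p); py <- colSums(p)
  mx <- sum((1:ng) * px); my <- sum((1:ng) * py)
  sx <- sqrt(sum(((1:ng) - mx)^2 * px))
  sy <- sqrt(sum(((1:ng) - my)^2 * py))
  energy <- 0; corr_num <- 0; inertia <- 0; entropy <- 0; idm <- 0
  hxy1 <- 0
  psum <- numeric(2 * ng); pdiff <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    pij <- p[i, j]
    energy <- energy + pij^2
    corr_num <- corr_num + (i - mx) * (j - my) * pij
    inertia <- inertia + (i - j)^2 * pij
    entropy <- entropy - pij * l2(pij)
    idm <- idm + pij / (1 + (i - j)^2)
    hxy1 <- hxy1 - pij * l2(px[i] * py[j])
    psum[i + j] <- psum[i + j] + pij
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + pij
  }
  sa <- sum((1:(2 * ng)) * psum)
  sv <- sum(((1:(2 * ng)) - sa)^2 * psum)
  se <- -sum(sapply(psum, function(q) q * l2(q)))
  da <- sum((0:(ng - 1)) * pdiff)
  dv <- sum(((0:(ng - 1)) - da)^2 * pdiff)
  de <- -sum(sapply(pdiff, function(q) q * l2(q)))
  hx <- -sum(sapply(px, function(q) q * l2(q)))
  hy <- -sum(sapply(py, function(q) q * l2(q)))
  c(energy = energy,
    correlation = if (sx > 0 && sy > 0) corr_num / (sx * sy) else 0,
    inertia = inertia, entropy = entropy,
    inverse_difference_moment = idm,
    sum_average = sa, sum_variance = sv, sum_entropy = se,
    difference_average = da, difference_variance = dv,
    difference_entropy = de,
    information_correlation =
      if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0)
}

# AUC as the fraction of correctly ordered positive/negative pairs
naive_auc <- function(pos, scores) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# a tiny PSI-BLAST-style ASCII PSSM text, with configurable column order
toy_pssm_text <- function(scores, residues, order = AA20,
                          percentages = NULL) {
  hdr <- paste0("      ",
                paste(sprintf("%4s", c(order,
                                       if (!is.null(percentages)) order)),
                      collapse = ""))
  rows <- vapply(seq_along(residues), function(i) {
    cells <- sprintf("%4d", scores[i, ])
    if (!is.null(percentages))
      cells <- c(cells, sprintf("%4d", percentages[i, ]))
    paste0(sprintf("%5d %s", i, residues[i]), paste(cells, collapse = ""))
  }, "")
  c("", "Last position-specific scoring matrix computed", hdr, rows, "")
}
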