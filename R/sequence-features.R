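#' Composition encodings of an amino-acid sequence
#'
#' The three composition features map a variable-length protein sequence to
#' a fixed-length vector of residue-pattern fractions:
#' * `aac()` — single-residue composition, `count(residue i) / N` with `N`
#'   the sequence length (20 values);
#' * `dipeptide_comp()` — ordered adjacent-pair composition,
#'   `count(pair i) / (N - 1)` (400 values);
#' * `gapped_pair_comp()` — ordered pairs separated by exactly `k`
#'   arbitrary residues ("AxB" patterns), `count / (N - 1 - k)`
#'   (400 values). `k = 0` reduces to the dipeptide composition.
#'
#' Residues outside the 20 standard types are never counted in a numerator
#' but still contribute to the literal denominators, so vectors over
#' standard-only sequences sum to exactly 1 and otherwise to less than 1.
#'
#' @param sequence Character scalar, amino-acid sequence (uppercase).
#' @param k Integer gap count, `>= 0`.
#' @return A named numeric vector (length 20 for `aac`, 400 for the pair
#'   encodings, named by residue / ordered residue pair in canonical
#'   alphabetical order).
#' @export
#' @examples
#' aac("AAAC")
#' dipeptide_comp("ACAC")[c("AC", "CA")]
#' gapped_pair_comp("ACDCA", k = 1)[c("AD", "CC", "DA")]
aac <- function(sequence) {
  idx <- seq_index(sequence)
  n <- length(idx)
  if (n < 1L) abort("aac: sequence must have length >= 1")
  setNames(tabulate(idx, nbins = 20L) / n, AA_ALPHABET20)
}

#' @rdname aac
#' @export
dipeptide_comp <- function(sequence) {
  gapped_pair_comp(sequence, k = 0L)
}

#' @rdname aac
#' @export
gapped_pair_comp <- function(sequence, k) {
  k <- as.integer(k)
  if (k < 0L) abort("gapped_pair_comp: k must be >= 0")
  idx <- seq_index(sequence)
  n <- length(idx)
  if (n < k + 2L)
    abort(paste0("gapped_pair_comp: sequence length must be >= k + 2 (k = ",
                 k, ", length = ", n, ")"))
  a <- idx[seq_len(n - 1L - k)]
  b <- idx[seq(k + 2L, n)]
  keep <- !is.na(a) & !is.na(b)
  counts <- tabulate((a[keep] - 1L) * 20L + b[keep], nbins = 400L)
  setNames(counts / (n - 1L - k), aa_pair_names())
}

# residue -> canonical index (NA for nonstandard letters)
seq_index <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    abort("sequence must be a single character string")
  match(strsplit(sequence, "")[[1]], AA_ALPHABET20)
}

#' Residue co-occurrence matrix
#'
#' Reshapes the gapped-pair composition into a 20 x 20 matrix analogous to
#' a grey-level co-occurrence matrix in texture analysis: rows index the
#' first residue of the pair, columns the second, in canonical alphabetical
#' order. The matrix is directional (counts ordered pairs, so it is not
#' symmetrised).
#'
#' @inheritParams aac
#' @return A 20 x 20 numeric matrix with residue dimnames; flattened
#'   row-major it equals `gapped_pair_comp(sequence, k)`.
#' @seealso [haralick_features()]
#' @export
cooccurrence_matrix <- function(sequence, k = 1L) {
  v <- gapped_pair_comp(sequence, k)
  matrix(v, nrow = 20L, ncol = 20L, byrow = TRUE,
         dimnames = list(first = AA_ALPHABET20, second = AA_ALPHABET20))
}

#' Haralick texture statistics of a co-occurrence matrix
#'
#' Twelve scalar texture statistics of a nonnegative co-occurrence matrix
#' `p(i, j)` (renormalised to sum 1): energy, correlation, inertia
#' (contrast), entropy, inverse difference moment, sum average, sum
#' variance, sum entropy, difference average, difference variance,
#' difference entropy, and the first information measure of correlation.
#' Logarithms are base 2 with the `0 * log 0 = 0` convention; correlation
#' is defined as 0 when a marginal has zero variance, and the information
#' measure as 0 when both marginal entropies are zero.
#'
#' @param P Square numeric matrix with nonnegative entries and positive
#'   sum, e.g. from [cooccurrence_matrix()].
#' @return Named numeric vector of length 12.
#' @export
haralick_features <- function(P) {
  if (!is.matrix(P) || nrow(P) != ncol(P))
    abort("haralick_features: P must be a square matrix")
  if (any(P < 0)) abort("haralick_features: entries must be nonnegative")
  s <- sum(P)
  if (s <= 0) abort("haralick_features: matrix sum must be positive")
  p <- P / s
  ng <- nrow(p)
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)
  mx <- sum(seq_len(ng) * px); my <- sum(seq_len(ng) * py)
  vx <- sum((seq_len(ng) - mx)^2 * px); vy <- sum((seq_len(ng) - my)^2 * py)

  log2z <- function(x) ifelse(x > 0, log2(x), 0)

  energy <- sum(p^2)
  correlation <- if (vx > 0 && vy > 0)
    (sum(i * j * p) - mx * my) / sqrt(vx * vy) else 0
  inertia <- sum((i - j)^2 * p)
  entropy <- -sum(p * log2z(p))
  idm <- sum(p / (1 + (i - j)^2))

  # sum / difference distributions over i + j and |i - j|
  psum <- vapply(2:(2 * ng), function(k) sum(p[i + j == k]), 0)
  pdiff <- vapply(0:(ng - 1), function(k) sum(p[abs(i - j) == k]), 0)
  ks <- 2:(2 * ng); kd <- 0:(ng - 1)
  sum_avg <- sum(ks * psum)
  sum_var <- sum((ks - sum_avg)^2 * psum)
  sum_ent <- -sum(psum * log2z(psum))
  diff_avg <- sum(kd * pdiff)
  diff_var <- sum((kd - diff_avg)^2 * pdiff)
  diff_ent <- -sum(pdiff * log2z(pdiff))

  hx <- -sum(px * log2z(px)); hy <- -sum(py * log2z(py))
  hxy1 <- -sum(p * log2z(outer(px, py)))
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0

  c(energy = energy, correlation = correlation, inertia = inertia,
    entropy = entropy, inverse_difference_moment = idm,
    sum_average = sum_avg, sum_variance = sum_var, sum_entropy = sum_ent,
    difference_average = diff_avg, difference_variance = diff_var,
    difference_entropy = diff_ent, information_correlation = imc1)
}

#' Physicochemical property fractions
#'
#' For each residue group in a property table, the fraction of the
#' sequence's residues belonging to that group (e.g. aromaticity is the
#' fraction of H, F, W, Y residues). With the default shipped table this
#' yields 48 values.
#'
#' @inheritParams aac
#' @param table Property table as returned by [read_property_table()];
#'   defaults to [default_property_table()].
#' @return Named numeric vector, one fraction per group.
#' @export
physicochemical_comp <- function(sequence, table = default_property_table()) {
  if (nrow(table) == 0L) abort("physicochemical_comp: empty property table")
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  if (n < 1L) abort("physicochemical_comp: sequence must have length >= 1")
  vapply(seq_len(nrow(table)),
         function(g) sum(chars %in% table$residues[[g]]) / n,
         0) |> setNames(table$group)
}

#' Sequence length feature
#'
#' @inheritParams aac
#' @return Named numeric vector of length 1 (`length` = residue count).
#' @export
length_feature <- function(sequence) {
  c(length = nchar(sequence))
}
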