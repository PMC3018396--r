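#' Binary domain-content encodings
#'
#' `domain_vector()` encodes which domains of a fixed vocabulary occur in a
#' protein (1 if the domain occurs at least once, else 0). For the full
#' yeast proteome the vocabulary has 1816 domains; any vocabulary can be
#' supplied.
#'
#' `repeated_domain_vector()` flags domain families that occur as a
#' repeated domain, i.e. two adjacent entries of the protein's ordered
#' domain list belonging to the same family.
#'
#' @param domains Character vector: the protein's domain identifiers in
#'   order along the sequence.
#' @param vocabulary Character vector defining vector positions.
#' @param lenient If `TRUE`, domains absent from the vocabulary are dropped
#'   with a warning instead of raising an error.
#' @return Named integer 0/1 vector over `vocabulary`.
#' @export
#' @examples
#' domain_vector(c("d2", "d3"), c("d1", "d2", "d3"))
#' repeated_domain_vector(c("A", "A", "B"), c("A", "B"))
domain_vector <- function(domains, vocabulary, lenient = FALSE) {
  if (length(vocabulary) == 0L) abort("domain_vector: empty vocabulary")
  domains <- check_vocab(domains, vocabulary, lenient, "domain")
  setNames(as.integer(vocabulary %in% domains), vocabulary)
}

#' @rdname domain_vector
#' @param families Optional named character vector mapping domain
#'   identifiers to family identifiers; by default each domain is its own
#'   family.
#' @export
repeated_domain_vector <- function(domains, vocabulary, families = NULL,
                                   lenient = FALSE) {
  if (length(vocabulary) == 0L)
    abort("repeated_domain_vector: empty vocabulary")
  fam <- if (is.null(families)) domains else unname(families[domains])
  fam <- check_vocab(fam, vocabulary, lenient, "domain family")
  repeated <- character()
  if (length(fam) >= 2L) {
    adj <- fam[-length(fam)] == fam[-1]
    repeated <- unique(fam[-length(fam)][adj])
  }
  setNames(as.integer(vocabulary %in% repeated), vocabulary)
}

check_vocab <- function(x, vocabulary, lenient, what) {
  unknown <- setdiff(x, vocabulary)
  if (length(unknown) > 0L) {
    if (!lenient)
      abort(paste0(what, " not in vocabulary: ",
                   paste(head(unknown, 3L), collapse = ", ")))
    warn(paste0("dropping ", length(unknown), " unknown ", what, "(s)"))
    x <- x[x %in% vocabulary]
  }
  x
}

#' Gene Ontology level membership encoding
#'
#' Binary membership of a protein's GO terms (one aspect, one level of the
#' GO graph) over a fixed term vocabulary. Unannotated proteins map to the
#' all-zero vector; terms outside the vocabulary are dropped with a
#' warning.
#'
#' @param terms Character vector of the protein's term ids at this level.
#' @param vocabulary Character vector of the level's terms, defining
#'   positions.
#' @return Named integer 0/1 vector over `vocabulary`.
#' @export
go_level_vector <- function(terms, vocabulary) {
  if (length(vocabulary) == 0L) abort("go_level_vector: empty vocabulary")
  terms <- check_vocab(terms, vocabulary, lenient = TRUE, "GO term")
  setNames(as.integer(vocabulary %in% terms), vocabulary)
}

#' Disorder-region summary features
#'
#' Four scalar summaries of a protein's disordered regions (0-based,
#' half-open residue intervals, assumed normalised/merged): the fraction of
#' residues disordered, the number of disordered regions, the longest
#' region length, and the mean region length. All four are zero for a
#' protein without disordered regions.
#'
#' @param intervals Data frame with integer columns `start` and `end`
#'   (half-open), or `NULL` / zero rows for none.
#' @param seq_length Protein length (residues).
#' @return Named numeric vector of length 4.
#' @export
#' @examples
#' disorder_features(data.frame(start = 10, end = 50), 100)
disorder_features <- function(intervals, seq_length) {
  if (is.null(intervals) || nrow(intervals) == 0L)
    return(c(disorder_fraction = 0, n_regions = 0,
             longest_region = 0, mean_region = 0))
  if (any(intervals$start < 0L) || any(intervals$end > seq_length) ||
      any(intervals$start >= intervals$end))
    abort("disorder_features: interval outside [0, sequence length)")
  len <- intervals$end - intervals$start
  c(disorder_fraction = sum(len) / seq_length,
    n_regions = nrow(intervals),
    longest_region = max(len),
    mean_region = mean(len))
}

#' Fixed-length PSSM encodings
#'
#' `pssm20()` summarises the profile's homologue composition: the
#' column-wise mean of the `L x 20` weighted-percentage block, rescaled to
#' fractions. When a profile carries no percentage block the composition is
#' approximated by the softmax of the position-averaged log-odds scores
#' (reported with a warning).
#'
#' `pssm400()` is the residue-conditioned profile encoding: for each of
#' the 20 standard residue types, the mean of the 20-dimensional score rows
#' at positions holding that residue (a zero block when the residue is
#' absent), blocks concatenated in canonical order and squashed entrywise
#' through the logistic function `1 / (1 + exp(-x))`, giving 400 values in
#' (0, 1).
#'
#' @param profile A [pssm_profile].
#' @return `pssm20()`: named numeric vector of length 20 (fractions);
#'   `pssm400()`: named numeric vector of length 400.
#' @export
pssm20 <- function(profile) {
  stopifnot(inherits(profile, "pssm_profile"))
  if (nrow(profile$scores) == 0L) abort("pssm20: empty profile")
  if (!is.null(profile$percentages)) {
    v <- colMeans(profile$percentages) / 100
  } else {
    warn("pssm20: no percentage block; using softmax of mean scores")
    m <- colMeans(profile$scores)
    e <- exp(m - max(m))
    v <- e / sum(e)
  }
  setNames(v, AA_ALPHABET20)
}

#' @rdname pssm20
#' @export
pssm400 <- function(profile) {
  stopifnot(inherits(profile, "pssm_profile"))
  idx <- match(strsplit(profile$sequence, "")[[1]], AA_ALPHABET20)
  if (length(idx) != nrow(profile$scores))
    abort("pssm400: profile rows do not match sequence length")
  blocks <- matrix(0, nrow = 20L, ncol = 20L)
  for (a in 1:20) {
    pos <- which(idx == a)
    if (length(pos) > 0L)
      blocks[a, ] <- colMeans(profile$scores[pos, , drop = FALSE])
  }
  v <- as.vector(t(blocks))   # block per residue type, canonical order
  setNames(stats::plogis(v), aa_pair_names())
}
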