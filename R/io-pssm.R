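#' Position-specific scoring matrix profile
#'
#' Container for one protein's PSI-BLAST profile. Profiles are stored as an
#' `L x 20` matrix of log-odds scores (one row per sequence position, one
#' column per standard amino acid in the canonical alphabetical order), with
#' an optional `L x 20` block of weighted observation percentages.
#'
#' @param scores Numeric `L x 20` matrix of log-odds scores.
#' @param sequence Length-`L` residue string the profile is aligned to.
#' @param percentages Optional numeric `L x 20` matrix of percentages
#'   (values in `[0, 100]`).
#' @return An object of class `pssm_profile`.
#' @export
pssm_profile <- function(scores, sequence, percentages = NULL) {
  scores <- as.matrix(scores)
  L <- nchar(sequence)
  if (nrow(scores) != L)
    abort(paste0("PSSM row count (", nrow(scores),
                 ") does not match sequence length (", L, ")"))
  if (ncol(scores) != 20L) abort("PSSM score matrix must have 20 columns")
  if (!is.null(percentages)) {
    percentages <- as.matrix(percentages)
    if (!all(dim(percentages) == dim(scores)))
      abort("percentage block must match score matrix dimensions")
  }
  colnames(scores) <- AA_ALPHABET20
  if (!is.null(percentages)) colnames(percentages) <- AA_ALPHABET20
  structure(list(scores = scores, percentages = percentages,
                 sequence = sequence),
            class = "pssm_profile")
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat("<pssm_profile> length", nrow(x$scores),
      if (is.null(x$percentages)) "(scores only)" else
        "(scores + percentages)", "\n")
  invisible(x)
}

#' Read a PSI-BLAST ASCII PSSM file
#'
#' Parses the plain-text profile written by PSI-BLAST's
#' `-out_ascii_pssm` / `-Q` option: header lines, an amino-acid column
#' header, then one row per position holding the position index, the query
#' residue, 20 log-odds scores and (usually) 20 weighted-percentage
#' columns. Columns are remapped from the file's header order to the
#' package's canonical alphabetical residue order, so the parsed matrix is
#' independent of the column order the file happens to use.
#'
#' @param path Path to an ASCII PSSM file.
#' @return A [pssm_profile] object.
#' @export
read_pssm <- function(path) {
  if (!file.exists(path)) abort(paste0("PSSM file not found: ", path))
  lines <- readLines(path, warn = FALSE)

  # locate the residue-letter header: >= 20 single-letter fields
  hdr_idx <- NA_integer_
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[[i]]), "[ \t]+")[[1]]
    if (length(toks) >= 20L && all(toks %in% c(LETTERS, letters))) {
      hdr_idx <- i
      break
    }
  }
  if (is.na(hdr_idx)) abort("PSSM format error: amino-acid header not found")
  hdr <- strsplit(trimws(lines[[hdr_idx]]), "[ \t]+")[[1]]
  file_order <- toupper(hdr[1:20])
  if (!setequal(file_order, AA_ALPHABET20))
    abort("PSSM format error: header does not list the 20 standard residues")

  rows <- list()
  residues <- character()
  pct_rows <- list()
  has_pct <- NA
  for (i in seq((hdr_idx + 1L), length(lines))) {
    if (i > length(lines)) break
    ln <- trimws(lines[[i]])
    if (ln == "") break
    toks <- strsplit(ln, "[ \t]+")[[1]]
    if (!grepl("^[0-9]+$", toks[1])) break   # footer (K, Lambda ...)
    if (length(toks) < 22L)
      abort(paste0("PSSM format error: truncated row at line ", i))
    vals <- suppressWarnings(as.numeric(toks[3:22]))
    if (anyNA(vals))
      abort(paste0("PSSM format error: non-numeric score at line ", i))
    if (is.na(has_pct)) has_pct <- length(toks) >= 42L
    if (has_pct) {
      if (length(toks) < 42L)
        abort(paste0("PSSM format error: truncated row at line ", i))
      pv <- suppressWarnings(as.numeric(toks[23:42]))
      if (anyNA(pv))
        abort(paste0("PSSM format error: non-numeric percentage at line ", i))
      pct_rows[[length(pct_rows) + 1L]] <- pv
    }
    rows[[length(rows) + 1L]] <- vals
    residues <- c(residues, toupper(toks[2]))
  }
  if (length(rows) == 0L) abort("PSSM format error: no data rows")

  remap <- match(AA_ALPHABET20, file_order)
  scores <- do.call(rbind, rows)[, remap, drop = FALSE]
  percentages <- if (isTRUE(has_pct))
    do.call(rbind, pct_rows)[, remap, drop = FALSE] else NULL
  pssm_profile(scores, paste(residues, collapse = ""), percentages)
}

#' Write a profile in PSI-BLAST ASCII PSSM layout
#'
#' Emits the subset of the `-out_ascii_pssm` layout that [read_pssm()]
#' consumes (used mainly by the synthetic-data generator).
#'
#' @param profile A [pssm_profile].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(profile, path) {
  stopifnot(inherits(profile, "pssm_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("", "Last position-specific scoring matrix computed"), con)
  pct <- profile$percentages
  hdr_letters <- if (is.null(pct)) AA_ALPHABET20 else
    c(AA_ALPHABET20, AA_ALPHABET20)
  writeLines(paste0("      ", paste(sprintf("%4s", hdr_letters),
                                    collapse = "")), con)
  res <- strsplit(profile$sequence, "")[[1]]
  for (i in seq_along(res)) {
    cells <- sprintf("%4d", round(profile$scores[i, ]))
    if (!is.null(pct)) cells <- c(cells, sprintf("%4d", round(pct[i, ])))
    writeLines(paste0(sprintf("%5d %s", i, res[i]),
                      paste(cells, collapse = "")), con)
  }
  writeLines("", con)
  invisible(path)
}
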