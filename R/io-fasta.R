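#' Read protein sequences from a FASTA file
#'
#' Wraps [Biostrings::readAAStringSet()] with the validation and
#' normalisation the rest of the package expects: sequences are uppercased,
#' whitespace inside records is stripped, and the record id is the first
#' whitespace-delimited token of the header line.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return A tibble with one row per record and columns `id` (character) and
#'   `sequence` (character, uppercase amino-acid letters). Record order is
#'   file order.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 yeast protein", "acde", ">p2", "MKLV"), f)
#' read_fasta(f)
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  scan_fasta_lines(lines)          # line-numbered format errors
  aas <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aas), "[ \t]+"), `[`, "", 1L)
  if (anyDuplicated(ids))
    abort(paste0("duplicate FASTA id: ", ids[duplicated(ids)][1L]))
  tibble::tibble(id = unname(ids),
                 sequence = unname(toupper(gsub("[ \t]", "",
                                                as.character(aas)))))
}

# validation pass so format errors carry a line number, which the
# Biostrings reader does not report
scan_fasta_lines <- function(lines) {
  in_record <- FALSE
  seq_seen <- FALSE
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "") next
    if (startsWith(ln, ">")) {
      if (in_record && !seq_seen)
        abort(paste0("FASTA format error at line ", i,
                     ": record with empty sequence"))
      if (trimws(substring(ln, 2)) == "")
        abort(paste0("FASTA format error at line ", i, ": empty header"))
      in_record <- TRUE
      seq_seen <- FALSE
    } else {
      if (!in_record)
        abort(paste0("FASTA format error at line ", i,
                     ": sequence data before any header"))
      seq_seen <- TRUE
    }
  }
  if (in_record && !seq_seen)
    abort("FASTA format error at last line: record with empty sequence")
  if (!in_record) abort("FASTA format error: no records found")
  invisible(TRUE)
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins A data frame with columns `id` and `sequence`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  aas <- Biostrings::AAStringSet(setNames(proteins$sequence, proteins$id))
  Biostrings::writeXStringSet(aas, path, width = 70L)
  invisible(path)
}
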