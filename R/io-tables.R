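#' Read the annotation tables for a protein set
#'
#' Loads the three tab-separated annotation artifacts the feature encoders
#' consume and normalises them:
#' * domains: `protein_id TAB semicolon-separated ordered domain ids`
#'   (order along the protein matters for repeated-domain detection);
#' * GO terms: `protein_id TAB level TAB term_id`;
#' * disorder: `protein_id TAB start TAB end`, 0-based half-open residue
#'   intervals, merged when they overlap.
#'
#' @param domains_path,go_path,disorder_path File paths; any may be `NULL`
#'   to skip that table.
#' @param ids Optional character vector of known protein ids; rows for other
#'   ids are kept with a warning.
#' @return A list with tibbles `domains` (`protein_id`, `position`,
#'   `domain`), `go` (`protein_id`, `level`, `term`) and `disorder`
#'   (`protein_id`, `start`, `end`).
#' @export
read_annotations <- function(domains_path = NULL, go_path = NULL,
                             disorder_path = NULL, ids = NULL) {
  out <- list(domains = empty_domains(), go = empty_go(),
              disorder = empty_disorder())
  if (!is.null(domains_path)) out$domains <- read_domains_tsv(domains_path)
  if (!is.null(go_path)) out$go <- read_go_tsv(go_path)
  if (!is.null(disorder_path)) out$disorder <- read_disorder_tsv(disorder_path)
  if (!is.null(ids)) {
    for (nm in names(out)) {
      unknown <- setdiff(unique(out[[nm]]$protein_id), ids)
      if (length(unknown) > 0L)
        warn(paste0(nm, " table: ", length(unknown),
                    " protein id(s) not in the dataset (kept): ",
                    paste(head(unknown, 3L), collapse = ", ")))
    }
  }
  out
}

empty_domains <- function() {
  tibble::tibble(protein_id = character(), position = integer(),
                 domain = character())
}
empty_go <- function() {
  tibble::tibble(protein_id = character(), level = integer(),
                 term = character())
}
empty_disorder <- function() {
  tibble::tibble(protein_id = character(), start = integer(),
                 end = integer())
}

read_domains_tsv <- function(path) {
  raw <- readr::read_tsv(path, col_names = c("protein_id", "domains"),
                         col_types = "cc", comment = "#", progress = FALSE)
  raw |>
    dplyr::mutate(domain = strsplit(.data$domains, ";", fixed = TRUE)) |>
    tidyr::unnest_longer("domain") |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::mutate(position = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("protein_id", "position", "domain")
}

read_go_tsv <- function(path) {
  readr::read_tsv(path, col_names = c("protein_id", "level", "term"),
                  col_types = "cic", comment = "#", progress = FALSE)
}

read_disorder_tsv <- function(path) {
  d <- readr::read_tsv(path, col_names = c("protein_id", "start", "end"),
                       col_types = "cii", comment = "#", progress = FALSE)
  bad <- which(d$start >= d$end | d$start < 0L)
  if (length(bad) > 0L)
    abort(paste0("disorder table: invalid interval at row ", bad[1L],
                 " (need 0 <= start < end)"))
  normalize_intervals(d)
}

# merge overlapping / touching half-open intervals per protein
normalize_intervals <- function(d) {
  d |>
    dplyr::arrange(.data$protein_id, .data$start, .data$end) |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::mutate(grp = cumsum(.data$start > dplyr::lag(cummax(.data$end),
                                                        default = -1L))) |>
    dplyr::group_by(.data$protein_id, .data$grp) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop") |>
    dplyr::select("protein_id", "start", "end")
}

#' Read and write class-label tables
#'
#' Labels are integers 1-4 coding NH, IC, PH and DH. The on-disk format is
#' a headerless TSV `protein_id TAB label`.
#'
#' @param path File path.
#' @return A tibble with columns `protein_id` (character) and `label`
#'   (integer in 1..4).
#' @export
read_labels <- function(path) {
  d <- readr::read_tsv(path, col_names = c("protein_id", "label"),
                       col_types = "ci", comment = "#", progress = FALSE)
  d$label <- validate_labels(d$label)
  d
}

#' @rdname read_labels
#' @param labels A data frame with columns `protein_id` and `label`.
#' @export
write_labels <- function(labels, path) {
  stopifnot(all(c("protein_id", "label") %in% names(labels)))
  validate_labels(labels$label)
  readr::write_tsv(labels[, c("protein_id", "label")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Read and write a feature matrix
#'
#' Feature matrices travel as TSV with a header row of feature names and
#' the protein id in the first column. Values are written in full decimal
#' precision so a write-read round trip is value-identical.
#'
#' @param path File path.
#' @return For `read_feature_matrix`, a numeric matrix with protein ids as
#'   row names and feature names as column names.
#' @export
read_feature_matrix <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(
    protein_id = readr::col_character(),
    .default = readr::col_double()), progress = FALSE)
  if (names(d)[1] != "protein_id")
    abort("feature matrix: first column must be 'protein_id'")
  m <- as.matrix(d[, -1, drop = FALSE])
  if (anyNA(m)) abort("feature matrix contains missing / NaN values")
  rownames(m) <- d$protein_id
  m
}

#' @rdname read_feature_matrix
#' @param x Numeric matrix (proteins x features) with row and column names.
#' @export
write_feature_matrix <- function(x, path) {
  if (anyNA(x) || any(!is.finite(x)))
    abort("feature matrix contains missing or non-finite values")
  d <- tibble::as_tibble(x, rownames = "protein_id")
  readr::write_tsv(d, path)
  invisible(path)
}

#' Read a vocabulary file
#'
#' One identifier per line; line order defines the vector position used by
#' the binary membership encoders.
#'
#' @param path File path.
#' @return Character vector of identifiers.
#' @export
read_vocabulary <- function(path) {
  v <- trimws(readLines(path, warn = FALSE))
  v <- v[v != "" & !startsWith(v, "#")]
  if (anyDuplicated(v)) abort("vocabulary contains duplicate identifiers")
  v
}

#' Read a residue property-group table
#'
#' TSV with columns `group TAB residues`, e.g. `aromatic TAB HFWY`. The
#' package ships a default 48-group table
#' (`property_groups48_synthetic.tsv`); see [default_property_table()].
#'
#' @param path File path.
#' @return A tibble with columns `group` (character) and `residues`
#'   (list of character vectors of one-letter codes).
#' @export
read_property_table <- function(path) {
  d <- readr::read_tsv(path, col_names = c("group", "residues"),
                       col_types = "cc", comment = "#", progress = FALSE)
  res <- strsplit(toupper(d$residues), "")
  bad <- !vapply(res, function(r) all(r %in% AA_ALPHABET20), TRUE)
  if (any(bad))
    abort(paste0("property table: non-standard residue in group ",
                 d$group[bad][1L]))
  tibble::tibble(group = d$group, residues = res)
}

#' Read a cost matrix from a TSV file
#'
#' Four whitespace-separated numeric columns, four rows, rows = true class,
#' columns = predicted class; `#` lines are comments. The package ships the
#' hub-prioritising default as `extdata/cost_matrix_hub_priority.tsv`
#' (identical to [hub_cost_matrix()]).
#'
#' @param path File path.
#' @return A validated 4x4 numeric cost matrix.
#' @export
read_cost_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != "" & !startsWith(trimws(lines), "#")]
  vals <- lapply(strsplit(trimws(lines), "[ \t]+"), as.numeric)
  L <- do.call(rbind, vals)
  dimnames(L) <- list(true = names(HUB_CLASSES),
                      predicted = names(HUB_CLASSES))
  validate_cost_matrix(L)
  L
}

#' Default 48-group physicochemical property table
#'
#' The published source for the 48 residue property groups does not list
#' them, so the package ships a synthetic stand-in assembled from standard
#' residue classifications (hydrophobicity, volume, polarity,
#' polarizability, charge, secondary-structure and accessibility classes,
#' plus classical chemical groups). The aromatic group is H, F, W, Y. The
#' table is only a default: any 48-row table can be supplied to
#' [physicochemical_comp()].
#'
#' @return A tibble as returned by [read_property_table()], 48 rows.
#' @export
default_property_table <- function() {
  read_property_table(system.file("extdata",
                                  "property_groups48_synthetic.tsv",
                                  package = "hubclass", mustWork = TRUE))
}
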