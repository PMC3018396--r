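#' Assemble a protein dataset
#'
#' Bundles the pieces the pipeline consumes: the proteins themselves, their
#' class labels, and optional annotations and profiles. All downstream
#' feature extraction aligns rows to `proteins$id` order.
#'
#' @param proteins Tibble with columns `id`, `sequence` (see
#'   [read_fasta()]).
#' @param labels Tibble with columns `protein_id`, `label` (1-4), one row
#'   per protein.
#' @param annotations Optional list with tibbles `domains`, `go`,
#'   `disorder` as returned by [read_annotations()].
#' @param pssms Optional named list of [pssm_profile] objects, names =
#'   protein ids.
#' @param vocab Optional list of vocabularies (element `domains`; elements
#'   named like `go_cc_1` for GO levels). Missing vocabularies are derived
#'   from the annotation tables at extraction time.
#' @return An object of class `hub_dataset`.
#' @export
hub_dataset <- function(proteins, labels, annotations = NULL, pssms = NULL,
                        vocab = list()) {
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  if (anyDuplicated(proteins$id)) abort("duplicate protein ids")
  if (any(nchar(proteins$sequence) < 1L)) abort("empty protein sequence")
  labels <- labels[match(proteins$id, labels$protein_id), ]
  if (anyNA(labels$protein_id)) abort("every protein needs a label")
  labels$label <- validate_labels(labels$label)
  if (is.null(annotations))
    annotations <- list(domains = empty_domains(), go = empty_go(),
                        disorder = empty_disorder())
  structure(list(proteins = proteins, labels = labels,
                 annotations = annotations, pssms = pssms, vocab = vocab),
            class = "hub_dataset")
}

#' @export
print.hub_dataset <- function(x, ...) {
  tab <- table(factor(x$labels$label, 1:4, names(HUB_CLASSES)))
  cat("<hub_dataset>", nrow(x$proteins), "proteins |",
      paste(names(tab), as.integer(tab), collapse = " "), "\n")
  invisible(x)
}

#' Load a dataset from an on-disk layout
#'
#' Reads the directory layout written by [generate_dataset()]:
#' `proteins.fasta`, `labels.tsv`, `domains.tsv`, `go.tsv`,
#' `disorder.tsv`, and one PSI-BLAST ASCII profile per protein under
#' `pssm/<id>.pssm`. Missing optional pieces are skipped.
#'
#' @param dir Dataset directory.
#' @return A [hub_dataset].
#' @export
load_dataset <- function(dir) {
  proteins <- read_fasta(file.path(dir, "proteins.fasta"))
  labels <- read_labels(file.path(dir, "labels.tsv"))
  p <- function(f) { f <- file.path(dir, f); if (file.exists(f)) f else NULL }
  ann <- read_annotations(p("domains.tsv"), p("go.tsv"), p("disorder.tsv"),
                          ids = proteins$id)
  pssm_dir <- file.path(dir, "pssm")
  pssms <- NULL
  if (dir.exists(pssm_dir)) {
    files <- list.files(pssm_dir, pattern = "\\.pssm$", full.names = TRUE)
    pssms <- lapply(files, read_pssm)
    names(pssms) <- sub("\\.pssm$", "", basename(files))
    pssms <- pssms[intersect(proteins$id, names(pssms))]
  }
  hub_dataset(proteins, labels, ann, pssms)
}

#' Names of the seventeen feature encodings
#'
#' The feature-set identifiers accepted by [extract_features()]: six
#' sequence encodings (`aac`, `dipeptides`, `pairs_1gap`, `pairs_2gaps`,
#' `haralick`, `physicochemical` -- the last with the sequence length
#' appended), the two domain encodings, six GO level encodings
#' (`go_{bp,cc,mf}_{1,2}`), `disorder`, and the two PSSM encodings.
#'
#' @return Character vector of length 17.
#' @export
feature_set_names <- function() {
  c("aac", "dipeptides", "pairs_1gap", "pairs_2gaps", "haralick",
    "physicochemical", "go_bp_1", "go_bp_2", "go_cc_1", "go_cc_2",
    "go_mf_1", "go_mf_2", "domains", "repeated_domains", "disorder",
    "pssm20", "pssm400")
}

#' Extract feature sets from a dataset
#'
#' Computes the requested feature encodings for every protein and returns
#' them as a feature collection: a named list of numeric matrices
#' (proteins x features), row-aligned across sets in dataset order. This
#' is the `X1..Xn` input representation of the classifier pipeline.
#'
#' @param dataset A [hub_dataset].
#' @param sets Character vector of encoding names (see
#'   [feature_set_names()]).
#' @param haralick_k Gap parameter of the co-occurrence matrix feeding the
#'   Haralick statistics (default 1).
#' @param property_table Property table for the physicochemical encoding.
#' @return An object of class `feature_collection`: named list of matrices
#'   with protein ids as row names.
#' @export
extract_features <- function(dataset, sets = feature_set_names(),
                             haralick_k = 1L,
                             property_table = default_property_table()) {
  stopifnot(inherits(dataset, "hub_dataset"))
  unknown <- setdiff(sets, feature_set_names())
  if (length(unknown) > 0L)
    abort(paste0("unknown feature set(s): ", paste(unknown, collapse = ", ")))
  ids <- dataset$proteins$id
  seqs <- dataset$proteins$sequence
  out <- lapply(setNames(sets, sets), function(s)
    extract_one_set(s, ids, seqs, dataset, haralick_k, property_table))
  structure(out, class = "feature_collection")
}

#' @export
print.feature_collection <- function(x, ...) {
  dims <- vapply(x, ncol, 0L)
  cat("<feature_collection>", length(x), "set(s),",
      nrow(x[[1]]), "proteins:\n")
  cat(paste0("  ", names(x), " (", dims, ")", collapse = "\n"), "\n")
  invisible(x)
}

seq_matrix <- function(ids, seqs, f) {
  m <- do.call(rbind, lapply(seqs, f))
  rownames(m) <- ids
  m
}

extract_one_set <- function(set, ids, seqs, dataset, haralick_k,
                            property_table) {
  ann <- dataset$annotations
  switch(set,
    aac = seq_matrix(ids, seqs, aac),
    dipeptides = seq_matrix(ids, seqs, dipeptide_comp),
    pairs_1gap = seq_matrix(ids, seqs, function(s) gapped_pair_comp(s, 1L)),
    pairs_2gaps = seq_matrix(ids, seqs, function(s) gapped_pair_comp(s, 2L)),
    haralick = seq_matrix(ids, seqs, function(s)
      haralick_features(cooccurrence_matrix(s, haralick_k))),
    physicochemical = seq_matrix(ids, seqs, function(s)
      c(physicochemical_comp(s, property_table), length_feature(s))),
    domains = domain_matrix(ids, ann$domains, dataset$vocab$domains,
                            repeated = FALSE),
    repeated_domains = domain_matrix(ids, ann$domains,
                                     dataset$vocab$domains, repeated = TRUE),
    go_bp_1 = go_matrix(ids, ann$go, "BP", 1L, dataset$vocab[["go_bp_1"]]),
    go_bp_2 = go_matrix(ids, ann$go, "BP", 2L, dataset$vocab[["go_bp_2"]]),
    go_cc_1 = go_matrix(ids, ann$go, "CC", 1L, dataset$vocab[["go_cc_1"]]),
    go_cc_2 = go_matrix(ids, ann$go, "CC", 2L, dataset$vocab[["go_cc_2"]]),
    go_mf_1 = go_matrix(ids, ann$go, "MF", 1L, dataset$vocab[["go_mf_1"]]),
    go_mf_2 = go_matrix(ids, ann$go, "MF", 2L, dataset$vocab[["go_mf_2"]]),
    disorder = disorder_matrix(ids, ann$disorder,
                               nchar(dataset$proteins$sequence)),
    pssm20 = pssm_matrix(ids, dataset$pssms, pssm20),
    pssm400 = pssm_matrix(ids, dataset$pssms, pssm400)
  )
}

domain_matrix <- function(ids, domains, vocab, repeated) {
  by_id <- split(domains$domain[order(domains$protein_id,
                                      domains$position)],
                 domains$protein_id[order(domains$protein_id,
                                          domains$position)])
  if (is.null(vocab)) vocab <- sort(unique(domains$domain))
  if (length(vocab) == 0L) abort("no domain vocabulary available")
  f <- if (repeated) repeated_domain_vector else domain_vector
  m <- do.call(rbind, lapply(ids, function(id)
    f(by_id[[id]] %||% character(), vocab, lenient = TRUE)))
  rownames(m) <- ids
  m
}

go_matrix <- function(ids, go, aspect, level, vocab) {
  rows <- go[go$level == level & startsWith(go$term, aspect), ]
  if (is.null(vocab)) vocab <- sort(unique(rows$term))
  if (length(vocab) == 0L)
    abort(paste0("no GO vocabulary for ", aspect, " level ", level))
  by_id <- split(rows$term, rows$protein_id)
  m <- do.call(rbind, lapply(ids, function(id)
    go_level_vector(by_id[[id]] %||% character(), vocab)))
  rownames(m) <- ids
  m
}

disorder_matrix <- function(ids, disorder, lengths) {
  m <- do.call(rbind, lapply(seq_along(ids), function(i) {
    iv <- disorder[disorder$protein_id == ids[i], , drop = FALSE]
    disorder_features(iv, lengths[i])
  }))
  rownames(m) <- ids
  m
}

pssm_matrix <- function(ids, pssms, f) {
  if (is.null(pssms)) abort("dataset carries no PSSM profiles")
  missing <- setdiff(ids, names(pssms))
  if (length(missing) > 0L)
    abort(paste0("missing PSSM profile for: ",
                 paste(head(missing, 3L), collapse = ", ")))
  m <- do.call(rbind, lapply(ids, function(id) f(pssms[[id]])))
  rownames(m) <- ids
  m
}
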