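# GO term-string rules restricting the universe to neural cell-surface
# proteins.  Matching is on term NAMES as literal strings (no GO-graph
# traversal): membrane terms are matched whole, neural terms by prefix,
# and exclusion strings as substrings that veto a neural prefix match.

MEMBRANE_TERMS <- c("integral component of plasma membrane",
                    "anchored component of external side of plasma membrane")
NEURAL_PREFIXES <- c("nervous", "neuron", "dendr", "axon", "synap")
NEURAL_EXCLUSIONS <- c("enteric", "autonomous", "synaptonem", "axonem",
                       "dendritic cell")

#' Does a GO term set mark a neural cell-surface protein?
#'
#' True iff the set contains one of the two plasma-membrane terms AND at
#' least one term that begins with `nervous`, `neuron`, `dendr`, `axon`
#' or `synap` without containing any of the exclusion strings `enteric`,
#' `autonomous`, `synaptonem`, `axonem` or `dendritic cell`.  Prefixes
#' are anchored at the term start; exclusions match anywhere in the term
#' and always veto that term.
#'
#' @param terms character vector of GO term names.
#' @param ignore_case lower-case everything before matching
#'   (default `FALSE`: GO names are conventionally lower-case already).
#' @return logical flag.
#' @examples
#' passes_surface_filter(c("integral component of plasma membrane",
#'                         "neuron projection"))        # TRUE
#' passes_surface_filter(c("integral component of plasma membrane",
#'                         "synaptonemal complex"))     # FALSE
#' @export
passes_surface_filter <- function(terms, ignore_case = FALSE) {
  if (!length(terms)) return(FALSE)
  terms <- as.character(terms)
  if (ignore_case) terms <- tolower(terms)
  membrane <- any(terms %in% MEMBRANE_TERMS)
  if (!membrane) return(FALSE)
  neural_hit <- vapply(terms, function(tm) {
    if (!any(startsWith(tm, NEURAL_PREFIXES))) return(FALSE)
    !any(vapply(NEURAL_EXCLUSIONS, grepl, logical(1), x = tm, fixed = TRUE))
  }, logical(1))
  any(neural_hit)
}

#' Expand a passing set to whole protein families
#'
#' Families are defined purely by accession code: two proteins belong to
#' the same family when their accession codes share the same first three
#' characters.  Every member of a family with at least one passing
#' member is included.
#'
#' @param passing character vector of protein ids that passed the filter.
#' @param records annotation data.frame with columns `id`, `accession`
#'   (and optionally `terms`).
#' @return character vector of ids (superset of `passing`), in `records`
#'   order.
#' @export
expand_families <- function(passing, records) {
  stopifnot(is.data.frame(records), all(c("id", "accession") %in% names(records)))
  missing <- setdiff(passing, records$id)
  if (length(missing))
    abort(paste0("passing id(s) absent from records: ",
                 paste(missing, collapse = ", ")), "humsub_unknown_id")
  prefix <- substr(records$accession, 1L, 3L)
  pass_prefix <- unique(prefix[records$id %in% passing])
  records$id[prefix %in% pass_prefix]
}

#' Apply the surface filter with family expansion
#'
#' @param records annotation data.frame (`id`, `accession`, `terms`
#'   pipe-joined string or list column).
#' @param substitutions_per_protein optional named integer vector of
#'   fixed-substitution counts per protein id.
#' @param ignore_case passed to [passes_surface_filter()].
#' @return list with `ids` (family-expanded passing set), `n_proteins`
#'   (its size) and `n_with_substitution` (members with >= 1 fixed
#'   substitution; `NA` when counts are not supplied).
#' @export
apply_filter <- function(records, substitutions_per_protein = NULL,
                         ignore_case = FALSE) {
  if (!nrow(records))
    return(list(ids = character(), n_proteins = 0L, n_with_substitution = 0L))
  term_sets <- annotation_term_sets(records)
  pass <- records$id[vapply(term_sets, passes_surface_filter, logical(1),
                            ignore_case = ignore_case)]
  ids <- if (length(pass)) expand_families(pass, records) else character()
  n_sub <- if (is.null(substitutions_per_protein)) NA_integer_ else {
    cnt <- substitutions_per_protein[ids]
    cnt[is.na(cnt)] <- 0L
    sum(cnt >= 1L)
  }
  list(ids = ids, n_proteins = length(ids), n_with_substitution = n_sub)
}

# terms column may be a list column or a pipe-joined character column
annotation_term_sets <- function(records) {
  if (is.list(records$terms)) return(records$terms)
  strsplit(as.character(records$terms), "|", fixed = TRUE)
}

#' Read / write a protein annotation table
#'
#' Plain TSV with columns `id`, `accession`, `terms`; GO term names are
#' pipe-joined within the `terms` field.
#'
#' @param path TSV file.
#' @return data.frame with `id`, `accession`, `terms` (pipe-joined).
#' @export
read_annotations <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  stopifnot(all(c("id", "accession", "terms") %in% names(df)))
  df
}

#' @rdname read_annotations
#' @param records annotation data.frame.
#' @export
write_annotations <- function(records, path) {
  if (is.list(records$terms))
    records$terms <- vapply(records$terms, paste, character(1), collapse = "|")
  write_tsv(records[, c("id", "accession", "terms")], path)
}
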