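# Intra-human variability: per-gene counts of non-synonymous variant
# records (dbSNP-like consequence classes) and a cluster-level summary
# contrasting them with fixed lineage substitutions.

VARIANT_CLASSES <- c("missense", "nonsense", "stop_lost", "frameshift",
                     "synonymous", "intron", "other")
NONSYN_CLASSES <- c("missense", "nonsense", "stop_lost", "frameshift")

#' Count intra-human variable positions for one gene
#'
#' Counts variant records in the non-synonymous classes (missense,
#' nonsense, stop-lost, frameshift).  By default every qualifying record
#' counts once (the sum of mutation records); with
#' `distinct_positions = TRUE` and a `position` column, multi-allelic
#' records at one position collapse to a single variable position.
#'
#' @param records data.frame with columns `class` (consequence class)
#'   and optionally `position`; rows for a single gene.
#' @param distinct_positions count distinct qualifying positions instead
#'   of records.
#' @return integer count.
#' @export
count_variable_positions <- function(records, distinct_positions = FALSE) {
  if (!nrow(records)) return(0L)
  bad <- setdiff(unique(records$class), VARIANT_CLASSES)
  if (length(bad))
    abort(paste0("unknown consequence class(es): ",
                 paste(bad, collapse = ", ")), "humsub_unknown_class")
  hit <- records$class %in% NONSYN_CLASSES
  if (distinct_positions) {
    if (is.null(records$position))
      abort("distinct_positions = TRUE requires a 'position' column",
            "humsub_missing_position")
    return(length(unique(records$position[hit])))
  }
  sum(hit)
}

#' Summarise variability across a gene cluster
#'
#' Pairs per-gene intra-human variability counts with fixed
#' human-lineage substitution counts, and reports range and median of
#' the variability distribution.  With an even gene count the median is
#' the mean of the two middle values.  When a focal gene is named, the
#' summary flags whether its variability exceeds the cluster median —
#' the diagnostic for a locally elevated mutational burden.
#'
#' @param per_gene_counts named integer vector: variability count per
#'   gene.
#' @param lineage_subs named integer vector over the same genes: fixed
#'   lineage substitutions per gene.
#' @param focal optional focal gene name.
#' @return list with `table` (gene, variability, lineage_substitutions),
#'   `min`, `max`, `median`, and when `focal` is given
#'   `focal_variability` and `focal_exceeds_median`.
#' @export
cluster_summary <- function(per_gene_counts, lineage_subs, focal = NULL) {
  if (!setequal(names(per_gene_counts), names(lineage_subs)) ||
      length(per_gene_counts) != length(lineage_subs))
    abort("variability and substitution tables must cover the same genes",
          "humsub_mismatched_ids")
  genes <- sort(names(per_gene_counts))
  v <- per_gene_counts[genes]
  out <- list(table = data.frame(gene = genes,
                                 variability = unname(v),
                                 lineage_substitutions = unname(lineage_subs[genes]),
                                 stringsAsFactors = FALSE),
              min = min(v), max = max(v),
              median = stats::median(v))
  if (!is.null(focal)) {
    if (!focal %in% genes)
      abort(sprintf("focal gene '%s' not in the cluster", focal),
            "humsub_unknown_id")
    out$focal_variability <- unname(v[focal])
    out$focal_exceeds_median <- unname(v[focal]) > out$median
  }
  out
}

#' Read / write a per-variant table
#'
#' TSV with columns `gene`, `class` and optionally `position`.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_variants <- function(path) {
  df <- read_tsv(path)
  stopifnot(all(c("gene", "class") %in% names(df)))
  df
}

#' @rdname read_variants
#' @param variants data.frame of variant records.
#' @export
write_variants <- function(variants, path) {
  write_tsv(variants, path)
}
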