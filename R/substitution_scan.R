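#' Aligned ortholog panel for one protein
#'
#' Container for the aligned sequences the substitution scan operates on:
#' a set of human haplotype protein sequences plus one reference sequence
#' for each of three outgroup species (by convention chimpanzee `PTR`,
#' orangutan `PAB` and rhesus macaque `MML`).  All sequences must be
#' aligned to equal length; the permitted alphabet is the 20 amino acids
#' plus the gap character `-` and the unknown residue `X`.
#'
#' @param protein protein identifier (single string).
#' @param human_seqs character vector of aligned human haplotype
#'   sequences; names are haplotype labels (generated when missing).
#' @param outgroup_seqs named character vector of exactly 3 aligned
#'   outgroup sequences.
#' @return An object of class `ortholog_panel`: a list with elements
#'   `protein`, `human`, `outgroup` and `length` (alignment columns).
#' @examples
#' p <- ortholog_panel("toy", c("MKI", "MKI"), c(PTR = "MKN", PAB = "MKN", MML = "MKN"))
#' find_fixed_substitutions(p)
#' @export
ortholog_panel <- function(protein, human_seqs, outgroup_seqs) {
  if (length(protein) != 1L || !nzchar(protein))
    abort("'protein' must be a single non-empty label", "humsub_invalid_panel")
  if (length(human_seqs) < 1L)
    abort("at least one human haplotype sequence is required",
          "humsub_invalid_panel")
  if (length(outgroup_seqs) != 3L)
    abort("exactly 3 outgroup sequences are required", "humsub_invalid_panel")
  if (is.null(names(outgroup_seqs)) || anyDuplicated(names(outgroup_seqs)))
    abort("outgroup sequences must carry unique species names",
          "humsub_invalid_panel")
  lens <- nchar(c(human_seqs, outgroup_seqs))
  if (length(unique(lens)) != 1L)
    abort("all panel sequences must have equal aligned length",
          "humsub_invalid_panel")
  if (lens[1] < 1L)
    abort("panel sequences must have length >= 1", "humsub_invalid_panel")
  bad <- setdiff(unique(strsplit(paste(c(human_seqs, outgroup_seqs),
                                       collapse = ""), "")[[1]]),
                 c(AA_ALPHABET, NO_CALL, "*"))
  if (length(bad))
    abort(paste0("invalid residue character(s): ",
                 paste(bad, collapse = " ")), "humsub_invalid_panel")
  if (is.null(names(human_seqs)))
    names(human_seqs) <- sprintf("HUM_%03d", seq_along(human_seqs))
  structure(list(protein = protein,
                 human = human_seqs,
                 outgroup = outgroup_seqs,
                 length = lens[1]),
            class = "ortholog_panel")
}

#' @export
print.ortholog_panel <- function(x, ...) {
  cat(sprintf("ortholog panel '%s': %d human haplotypes, outgroups %s, %d aligned columns\n",
              x$protein, length(x$human),
              paste(names(x$outgroup), collapse = "/"), x$length))
  invisible(x)
}

#' Consensus residue of the three outgroup species
#'
#' @param residues character vector of exactly 3 single residues.
#' @param mode `"unanimous"` (all three identical) or `"majority"` (at
#'   least 2 of 3 agree).  Gap and `X` never form a consensus.
#' @return The consensus residue, or `NA_character_` when no consensus
#'   exists under the chosen mode.
#' @examples
#' outgroup_consensus(c("N", "N", "S"), "majority")   # "N"
#' outgroup_consensus(c("N", "N", "S"), "unanimous")  # NA
#' @export
outgroup_consensus <- function(residues, mode = c("unanimous", "majority")) {
  mode <- match.arg(mode)
  stopifnot(length(residues) == 3L)
  residues <- as.character(residues)
  if (any(residues %in% NO_CALL)) {
    # a gap/unknown outgroup can still leave a 2-of-3 majority,
    # but never a unanimous call
    if (mode == "unanimous") return(NA_character_)
  }
  callable <- residues[!residues %in% NO_CALL]
  if (mode == "unanimous") {
    if (length(unique(residues)) == 1L) return(residues[1])
    return(NA_character_)
  }
  tab <- table(callable)
  if (!length(tab) || max(tab) < 2L) return(NA_character_)
  names(tab)[which.max(tab)]
}

#' Residue fixed across all human haplotypes at one alignment column
#'
#' @param column character vector of residues, one per human haplotype.
#' @return The shared residue when every haplotype carries the same
#'   non-gap, non-`X` residue; `NA_character_` otherwise.
#' @export
is_fixed_in_humans <- function(column) {
  if (!length(column))
    abort("empty human column", "humsub_invalid_panel")
  column <- as.character(column)
  if (any(column %in% NO_CALL)) return(NA_character_)
  if (length(unique(column)) != 1L) return(NA_character_)
  column[1]
}

#' Scan a panel for fixed human-lineage substitutions
#'
#' A position is reported when (i) every human haplotype carries the same
#' residue, (ii) the outgroup species reach a consensus under the chosen
#' mode, and (iii) the two residues differ.  Columns containing a gap or
#' `X` in any human haplotype or (for unanimous mode) any outgroup are
#' skipped: they correspond to positions that cannot be aligned across
#' all four genomes and never yield a call.
#'
#' Reported positions are 1-based on the ungapped first human haplotype
#' (the reference), so they match protein coordinates even when the
#' alignment contains gap columns.
#'
#' @param panel an [ortholog_panel].
#' @param mode consensus mode, see [outgroup_consensus()].
#' @return data.frame with columns `position`, `ancestral`, `human`,
#'   `weight` (NA; filled by the scoring stage) and `domain` (NA), in
#'   ascending position order.
#' @export
find_fixed_substitutions <- function(panel, mode = c("unanimous", "majority")) {
  mode <- match.arg(mode)
  stopifnot(inherits(panel, "ortholog_panel"))
  hum <- do.call(rbind, strsplit(unname(panel$human), ""))
  out <- do.call(rbind, strsplit(unname(panel$outgroup), ""))
  ref <- hum[1, ]
  # protein coordinate of each alignment column on the ungapped reference
  ref_pos <- cumsum(ref != "-")

  hum_ok <- colSums(matrix(hum %in% NO_CALL, nrow = nrow(hum))) == 0L
  hum_fixed <- hum_ok & colSums(hum != rep(hum[1, ], each = nrow(hum))) == 0L

  out_ok <- colSums(matrix(out %in% NO_CALL, nrow = 3L)) == 0L
  if (mode == "unanimous") {
    anc_ok <- out_ok & out[1, ] == out[2, ] & out[2, ] == out[3, ]
    anc <- ifelse(anc_ok, out[1, ], NA_character_)
  } else {
    anc <- apply(out, 2L, outgroup_consensus, mode = "majority")
    anc[!out_ok] <- NA_character_  # unalignable columns never yield a call
  }

  hit <- hum_fixed & !is.na(anc) & hum[1, ] != anc
  idx <- which(hit)
  data.frame(position = ref_pos[idx],
             ancestral = anc[idx],
             human = hum[1, idx],
             weight = rep(NA_integer_, length(idx)),
             domain = rep(NA_character_, length(idx)),
             stringsAsFactors = FALSE)
}

#' Translate a coding sequence with the standard genetic code
#'
#' @param cds nucleotide string (`ACGT`; `N` tolerated, ambiguous codons
#'   translate to `X`).  Length must be a multiple of 3.
#' @return amino-acid string; stop codons appear as `*`.
#' @examples
#' translate_cds("ATGAATATT")  # "MNI"
#' @export
translate_cds <- function(cds) {
  stopifnot(length(cds) == 1L)
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L)
    abort("CDS length must be a multiple of 3", "humsub_invalid_cds")
  if (grepl("[^ACGTN]", cds))
    abort("CDS may contain only A/C/G/T/N", "humsub_invalid_cds")
  if (!nchar(cds)) return("")
  aa <- Biostrings::translate(Biostrings::DNAString(cds),
                              if.fuzzy.codon = "solve")
  as.character(aa)
}

#' Read an aligned ortholog panel from FASTA
#'
#' Human haplotype records are identified by an id prefix (default
#' `HUM_`); all remaining records are taken as outgroups and there must
#' be exactly three of them.
#'
#' @param path FASTA file.
#' @param protein protein label; defaults to the file name without
#'   extension.
#' @param human_prefix id prefix marking human haplotype records.
#' @return an [ortholog_panel].
#' @export
read_panel_fasta <- function(path, protein = NULL, human_prefix = "HUM_") {
  seqs <- Biostrings::readAAStringSet(path)
  ids <- names(seqs)
  is_hum <- startsWith(ids, human_prefix)
  if (!any(is_hum))
    abort(sprintf("no records with human prefix '%s' in %s",
                  human_prefix, path), "humsub_invalid_panel")
  if (is.null(protein))
    protein <- sub("\\.[^.]*$", "", basename(path))
  hum <- as.character(seqs[is_hum]); names(hum) <- ids[is_hum]
  out <- as.character(seqs[!is_hum]); names(out) <- ids[!is_hum]
  ortholog_panel(protein, hum, out)
}

#' Write an ortholog panel to FASTA
#'
#' @param panel an [ortholog_panel].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_panel_fasta <- function(panel, path) {
  stopifnot(inherits(panel, "ortholog_panel"))
  seqs <- Biostrings::AAStringSet(c(panel$human, panel$outgroup))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
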