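# Published worked example: the 12 fixed human-lineage substitutions in
# beta-protocadherin 11 (PCDHB11, 797 residues), and the ranking table of
# neural cell-surface proteins they belong to.  These published values
# anchor the weight calibration and the scoring arithmetic.

#' The 12 fixed human-lineage substitutions of PCDHB11
#'
#' Positions are 1-based protein coordinates; `ancestral` is the
#' consensus residue of chimpanzee, orangutan and rhesus macaque,
#' `human` the residue fixed across 100 human haplotypes.  `weight` is
#' the published exchange-rareness weight and `domain` the protein
#' domain (signal peptide, extracellular cadherin repeats EC1-EC3,
#' cytoplasmic).  Nine of the twelve changes fall in EC2/EC3, the
#' domains that control protocadherin binding specificity.
#'
#' @return 12-row data.frame: `position`, `ancestral`, `human`,
#'   `weight`, `domain`.
#' @export
pcdhb11_substitutions <- function() {
  data.frame(
    position  = c(4L, 106L, 134L, 185L, 213L, 252L, 263L, 281L, 304L,
                  334L, 336L, 724L),
    ancestral = c("E", "F", "L", "N", "T", "P", "T", "L", "T", "R", "Q", "R"),
    human     = c("Q", "L", "S", "I", "S", "R", "I", "F", "R", "I", "H", "S"),
    weight    = c(3L, 5L, 11L, 12L, 3L, 10L, 8L, 5L, 8L, 12L, 4L, 8L),
    domain    = c("Signal peptide", "EC1", "EC2", "EC2", "EC2", "EC3",
                  "EC3", "EC3", "EC3", "EC3", "EC3", "Cytoplasmic"),
    stringsAsFactors = FALSE)
}

#' Length of the PCDHB11 protein in residues
#' @return integer, 797.
#' @export
pcdhb11_length <- function() 797L

#' Reconstruct a PCDHB11-like ortholog panel
#'
#' Builds a 797-residue panel in which the human haplotypes carry the 12
#' published human residues and all three outgroups the published
#' consensus residues, with human and outgroups identical at every other
#' position (a deterministic placeholder backbone cycles through the
#' amino-acid alphabet).  Scanning this panel recovers exactly the 12
#' substitutions, making it the canonical end-to-end check of the scan.
#'
#' @param n_human number of human haplotype sequences (default 100).
#' @return an [ortholog_panel].
#' @export
pcdhb11_panel <- function(n_human = 100L) {
  subs <- pcdhb11_substitutions()
  len <- pcdhb11_length()
  backbone <- rep_len(AA_ALPHABET, len)
  anc <- backbone; anc[subs$position] <- subs$ancestral
  hum <- backbone; hum[subs$position] <- subs$human
  human_seq <- paste(hum, collapse = "")
  anc_seq <- paste(anc, collapse = "")
  ortholog_panel("PCDHB11",
                 setNames(rep(human_seq, n_human),
                          sprintf("HUM_%03d", seq_len(n_human))),
                 c(PTR = anc_seq, PAB = anc_seq, MML = anc_seq))
}

#' Published ranking of neural cell-surface proteins
#'
#' The 23 top-ranked proteins by length-normalised weighted substitution
#' score: substitution count, protein length and weighted substitution
#' sum for each.  Per-length ratios are derived columns and are
#' recomputed (not stored) so the table carries exact integers only.
#'
#' @return data.frame with `protein`, `n_subst`, `length`,
#'   `weighted_sum` in published rank order.
#' @export
neural_surface_scores <- function() {
  data.frame(
    protein = c("PCDHB11", "ICAM1", "HTR3E", "HRH1", "DRD5", "PCDHB13",
                "GLRA4", "HOMER3", "PCDHB6", "VIPR1", "CCKAR", "PCDHB12",
                "OXYR", "GRIN3A", "PCDHB10", "SEMA5B", "PCDHA5",
                "PCDHB14", "GRIN2C", "PCDHA2", "CD44", "PCDHB15",
                "PCDH15"),
    n_subst = c(12L, 6L, 4L, 5L, 5L, 6L, 4L, 2L, 5L, 2L, 2L, 4L, 3L, 6L,
                3L, 5L, 4L, 4L, 4L, 4L, 3L, 4L, 9L),
    length = c(797L, 532L, 456L, 487L, 477L, 798L, 417L, 361L, 794L,
               457L, 428L, 797L, 389L, 1115L, 797L, 1151L, 936L, 798L,
               1236L, 948L, 742L, 787L, 1955L),
    weighted_sum = c(89L, 41L, 33L, 31L, 30L, 47L, 24L, 19L, 40L, 20L,
                     18L, 30L, 14L, 38L, 27L, 32L, 26L, 21L, 32L, 23L,
                     17L, 18L, 43L),
    stringsAsFactors = FALSE)
}
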