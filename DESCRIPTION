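Package: humsub
Title: Ranking Human-Lineage Amino Acid Substitutions in Neural
    Cell-Surface Proteins
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects amino-acid substitutions that are fixed on the human
    lineage from aligned ortholog panels (human haplotypes versus
    chimpanzee, orangutan and rhesus macaque), restricts the protein
    universe to neural cell-surface proteins via Gene Ontology term-string
    rules with protein-family expansion, weights each substitution by the
    evolutionary rareness of the amino-acid exchange derived from a BLOSUM
    substitution matrix, and ranks proteins by length-normalised weighted
    scores.  Also counts intra-human non-synonymous variability per gene,
    and quantifies cell-aggregation assay micrographs: triangle
    auto-thresholding, connected-component cluster areas, spherical-model
    cell-count cutoffs, reference-normalised adhesive strength and
    two-channel mixed-cluster fractions, with ANOVA-based condition
    testing.  A seeded synthetic-data generator provides ortholog panels,
    variant tables, annotation tables and cluster images with known ground
    truth so that every stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    EBImage,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
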