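# humsub

Ranking human-lineage amino-acid substitutions in neural cell-surface
proteins, and quantifying the cell-aggregation assays used to test
them.

## What this package is for

Comparing 100 human haplotype protein sequences against the reference
proteomes of chimpanzee, orangutan and rhesus macaque identifies
positions where every modern human carries one residue and the three
outgroups agree on another — *fixed human-lineage substitutions*.
`humsub` is for evolutionary biologists and molecular neuroscientists
who want to rank candidate proteins by how much they changed on the
human lineage, with substitutions weighted by how evolutionarily rare
each amino-acid exchange is, and to analyse the downstream functional
readouts.

The pipeline:

1. **Scan** (`find_fixed_substitutions`) — for each aligned ortholog
   panel, call position *i* when all human haplotypes share residue
   *h<sub>i</sub>*, the outgroups reach consensus *a<sub>i</sub>*
   (unanimous by default), and *h<sub>i</sub> ≠ a<sub>i</sub>*.
2. **Filter** (`passes_surface_filter`, `expand_families`) — keep
   proteins annotated with "integral component of plasma membrane" (or
   the anchored-component variant) plus a neural GO term
   (`nervous`/`neuron`/`dendr`/`axon`/`synap` prefixes, with
   `synaptonem`-style exclusions), expanded to whole UniProt-prefix
   families.
3. **Score and rank** (`derive_weights`, `score_protein`,
   `rank_proteins`) — each exchange *a → h* gets a rareness weight from
   BLOSUM100,

   *w*(*s*) = clamp(round(5 − *s*), 3, 15),

   so the most common exchanges weigh 3 and the least common 15; per
   protein, *W* = Σ *w* and the ranking key is *W*/length.
4. **Variability** (`count_variable_positions`, `cluster_summary`) —
   intra-human non-synonymous variant counts per gene (missense +
   nonsense + stop-lost + frameshift), compared against the lineage
   substitutions.
5. **Imaging** (`triangle_threshold`, `extract_clusters`,
   `cell_count_cutoff`, `mixed_fraction`, `condition_tests`) —
   cell-aggregation micrograph quantification under the spherical
   cluster model: a cluster of *N* cells projects area
   *A₁·N*^(2/3), giving cutoffs 696 px (10 cells) and 1448 px
   (30 cells) at the 150 px single-cell area.

A seeded synthetic-data generator (`gen_ortholog_panel`,
`gen_variant_table`, `gen_cluster_image`, …) produces inputs with known
ground truth for every stage, and `run_pipeline()` orchestrates the
arms from one YAML config with a deterministic run manifest.

## Worked example

```r
library(humsub)

wt <- derive_weights(blosum100())
score_protein(pcdhb11_substitutions(), pcdhb11_length(), wt,
              protein = "PCDHB11")
#>   protein n_subst length subst_per_length weighted_sum weighted_per_length
#> 1 PCDHB11      12    797       0.01505646           89           0.1116688
```

The 12 substitutions of β-protocadherin 11 carry a weighted sum of 89;
per residue that is 0.112 — the top of the neural surface-protein
ranking (0.015 substitutions per residue unweighted):

```r
head(rank_proteins(neural_surface_scores()), 3)
#>   rank protein n_subst length weighted_sum subst_per_length weighted_per_length
#> 1    1 PCDHB11      12    797           89       0.01505646          0.11166876
#> 2    2   ICAM1       6    532           41       0.01127820          0.07706767
#> 3    3   HTR3E       4    456           33       0.00877193          0.07236842
```

Scanning a panel that plants those 12 differences (100 human
haplotypes vs the consensus-reverted sequence in all three outgroups)
recovers exactly them:

```r
nrow(find_fixed_substitutions(pcdhb11_panel()))
#> [1] 12
```

And the spherical-model size-class boundaries used by the imaging arm:

```r
cell_count_cutoff(150, c(10, 30))
#> [1]  696 1448
```

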