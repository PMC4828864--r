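---
title: "Methods: ranking human-lineage substitutions and quantifying cell aggregation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ranking human-lineage substitutions and quantifying cell aggregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(humsub)
```

## The scientific problem

Almost half of all human proteins carry at least one amino acid at which
every sampled modern human agrees while the great-ape outgroups agree on
a different residue.  Such *fixed human-lineage substitutions* are the
raw material for asking which proteins changed most during human
evolution.  `humsub` implements the complete desk pipeline for this
question, specialised to neural cell-surface proteins, together with
the image quantification used to test the functional consequences of
the top candidate (the β-protocadherin PCDHB11) in a cell-aggregation
assay.

The pipeline has three arms:

1. **Genomic arm** — scan aligned ortholog panels for fixed
   substitutions, restrict to brain cell-surface proteins via Gene
   Ontology term strings, weight each substitution by the evolutionary
   rareness of the amino-acid exchange, and rank proteins.
2. **Variability arm** — count intra-human non-synonymous variant
   records per gene to test whether a candidate sits in a mutational
   hot spot.
3. **Imaging arm** — quantify cell-aggregation micrographs: triangle
   auto-threshold, connected-component areas, spherical-model cell
   counts, reference-normalised adhesive strength, and two-channel
   mixed-cluster fractions.

A seeded synthetic-data generator supplies inputs with known ground
truth for every arm, so the whole pipeline is testable offline.

## Detecting fixed substitutions

A panel for one protein holds `n` aligned human haplotype sequences
(100 in the original design) and one aligned sequence for each of three
outgroups: chimpanzee, orangutan and rhesus macaque.  A position is
called when

* all human haplotypes carry the same residue (*fixation*),
* the outgroups agree on a residue (*ancestral consensus*), and
* the two differ.

Consensus is **unanimous** by default (all three outgroups identical);
a 2-of-3 **majority** mode is provided because different studies use
either convention.  Columns with a gap or `X` in any sequence are
skipped, never called: they correspond to positions that cannot be
aligned across all four genomes.  Coordinates are 1-based on the
ungapped first human haplotype, matching protein numbering.  Panels
arrive aligned; computing alignments is out of scope.  A CDS input is
translated with the standard genetic code first
(`translate_cds()`), then scanned at the protein level — each changed
residue counts once, regardless of how many base changes produced it.

## The cell-surface filter

Annotation is by GO term *names* as literal strings, matching the
published procedure (which quotes names, not IDs, and does no graph
propagation).  A protein passes when it has

* "integral component of plasma membrane" **or** "anchored component of
  external side of plasma membrane", **and**
* some term beginning with `nervous`, `neuron`, `dendr`, `axon` or
  `synap` that does not contain `enteric`, `autonomous`, `synaptonem`,
  `axonem` or `dendritic cell`.

Exclusion strings always veto the term they occur in — "synaptonemal
complex" never qualifies — but do not poison other qualifying terms of
the same protein.  Prefix matching is anchored and case-sensitive by
default (`ignore_case = TRUE` lowers everything first).  Because
surface annotation is incomplete, families are then expanded: every
protein whose accession code shares its first three characters with a
passing protein's code is pulled in.  This is a deliberately blunt,
literal rule; a GO-graph-aware mode would be a natural extension but is
intentionally not implemented, to keep the filter identical to the
published one.

## Exchange-rareness weights

The BLOSUM100 matrix scores amino-acid exchanges between proteins at
≥ 99% identity — the human/chimpanzee regime — so a *low* score marks
an evolutionarily *rare* exchange.  Scores are converted to integer
weights on 3..15, increasing with rareness:

$$w(s) = \mathrm{clamp}\big(\mathrm{round}(5 - s),\ 3,\ 15\big)$$

The constants were calibrated once, by brute-force search over rounded
affine maps, against the 12 published PCDHB11 pair weights, and then
frozen; the frozen map reproduces all 12 exactly (e.g. Glu→Gln, score
2, weight 3; Asn→Ile, score −7, weight 12).  On the bundled standard
BLOSUM100 the least common exchange (score −10) maps to 15 and the ten
most exchangeable pairs (scores 2..4, e.g. Ile/Val, Phe/Tyr) share the
floor weight 3 — "the most common exchanges" all weigh 3, the least
common 15.  Rounding is half-away-from-zero; with integer log-odds
scores the map is exact and rounding only matters for the rank-based
path below.

Per protein, the weights of all fixed substitutions are summed
(`weighted_sum`) and normalised by protein length
(`weighted_per_length`), alongside the unweighted count and its
normalisation.  For PCDHB11: 12 substitutions, weighted sum 89, and
89/797 ≈ 0.112 per residue.

**Alternative matrices.**  Ranking robustness is assessed by rerunning
with a different matrix through the same interface.  BLOSUM62 is
bundled; for rate/exchangeability matrices on other scales (e.g.
JTT-derived), `derive_weights(method = "rank")` first replaces scores
by their ranks and then maps the extremes to 3 and 15, which removes
any scale dependence.

**Ranking.**  Descending stable sort with ties broken by substitution
count (descending) then protein id (ascending).  Ratios are recomputed
from the integer columns before sorting so that rankings never depend
on rounded printed values — on the published table the exact ratios
are strictly decreasing, and ranking by `weighted_per_length`
reproduces the published row order.  `compare_rankings()` reports the
Spearman correlation between two orderings.

## Intra-human variability

Per gene, the variability count is the number of variant records in the
non-synonymous classes missense, nonsense, stop-lost and frameshift.
The default counts *records* (the sum of such mutations, following the
published definition); `distinct_positions = TRUE` instead counts
distinct qualifying positions, collapsing multi-allelic entries, for
data where "variable positions" is the intended unit.  The cluster
summary pairs these counts with fixed lineage substitutions per gene
and reports min, max and median (even counts: mean of the middle two),
plus whether a focal gene exceeds the cluster median — the diagnostic
for a locally elevated mutational burden.

## Image quantification

**Triangle threshold.**  On the 256-bin intensity histogram, a line is
drawn from the peak to the far end of the nonzero range on the
longer-tail side; the threshold is the bin maximising perpendicular
distance to that line, offset one bin toward the tail.  Frozen
conventions: peak = first maximal bin; tail side = larger peak-to-end
distance, ties to the brighter side; equidistant bins resolve nearest
the peak.  These conventions are oracle-tested against an exhaustive
distance search; they are *not* claimed bit-identical to any particular
ImageJ plugin build, whose pre-smoothing and background flags vary.

**Clusters.**  Connected components of the thresholded mask use
8-connectivity by default (the common particle-analysis convention;
4-connectivity available), and components under 100 px are discarded —
the published export floor.  The single-cell area is estimated as the
mode (10 px bins, ties to the smaller bin) of control-condition cluster
areas, 150 px in the original data.

**Spherical model.**  A cluster of $N$ close-packed cells is modelled
as a sphere, so projected area $\approx A_1 N^{2/3}$ for single-cell
area $A_1$.  Cutoffs are rounded to the nearest integer: at
$A_1 = 150$, 10 cells → 696 px and 30 cells → 1448 px.  Size classes:
small $<$ 696, medium 696–1448 (closed on both ends, so "10–30 cells"
includes its endpoints), large $>$ 1448.  The adhesion readout is
`fraction_ge10`, the proportion of clusters with ≥ 10 cells; adhesive
strength normalises it to the same-day, same-fluorophore
strongly-adhesive reference condition.

**Mixing.**  For two-population experiments the green and red masks are
combined by logical OR, components of the union ≥ 100 px are
enumerated (the floor is applied *after* the union, the reading adopted
here since the original order is unstated), and a cluster is *mixed*
when it overlaps both channel masks by at least one pixel.  The mixed
fraction over all clusters measures cross-population adhesion.

**Statistics.**  `condition_tests()` delegates to stock routines:
one-way ANOVA with Tukey HSD on normalised strengths, and for mixing
data a two-way ANOVA on the two population identities with interaction,
plus within-subpanel linear-model contrasts against a named control
with Bonferroni correction.

## The synthetic-data generator

The generator exists so every pipeline property can be tested against
planted ground truth.

* **Panels** — a random consensus backbone; planted substitutions make
  all human haplotypes carry the derived residue and all outgroups the
  ancestral one; background polymorphism flips individual haplotypes at
  non-planted sites with a per-site rate.  Noise deliberately never
  touches planted sites, so fixation testing is independent of the
  rate; a separate `break_fixation` flag produces the negative case.
  Default panel size is 100 haplotypes, the original design.
* **Variant tables** — rows drawn to match requested per-gene class
  totals exactly, shuffled under the seed.
* **Cluster images** — non-overlapping disks whose areas follow the
  spherical law exactly: a cluster drawn with $N$ cells occupies
  precisely $\mathrm{round}(150\,N^{2/3})$ pixels, rasterised as the
  nearest-to-centre pixels with a deterministic tie-break.  (Exact-area
  rasterisation was chosen over a midpoint-circle fill so ground-truth
  areas carry no ±1 px slack.)  Cells per cluster default to a
  zero-truncated geometric distribution — the long-tailed
  small-cluster regime of a weakly adhesive suspension culture — and a
  `fixed` option pins $N$ for calibration tests.  Each cluster belongs
  to the green or red channel, or to both with probability
  `channel_mix_rate` (its pixels split between the channels, both
  halves non-empty).
* **Intensities** — background 20, foreground 220, Gaussian noise
  SD 2, clamped to 8-bit.  The noise default is small relative to the
  200-unit contrast by design: channel presence in the mixing analysis
  is single-pixel sensitive, and the generator emulates clean,
  well-exposed fluorescence fields in which single-pixel membership is
  unambiguous.  At substantially higher noise the adaptive threshold
  (≈ background + 3.3 SD) lets isolated noise pixels through at a rate
  that biases the mixed fraction upward — a real phenomenon the
  vignette's *Limitations* section returns to.

All draws come from one seeded stream per call; generators restore the
caller's RNG state, and identical spec + seed gives bit-identical
output.

## Worked example

```{r}
wt <- derive_weights(blosum100())
score_protein(pcdhb11_substitutions(), pcdhb11_length(), wt,
              protein = "PCDHB11")

cell_count_cutoff(150, c(10, 30))

subs <- find_fixed_substitutions(pcdhb11_panel())
nrow(subs)

head(rank_proteins(neural_surface_scores()), 3)
```

## Numerical choices and degenerate inputs

* Rounding is half-away-from-zero throughout (cutoffs, weights).
* A constant off-diagonal matrix has no weight range and is rejected.
* Empty histograms, empty cluster lists, zero-reference normalisation
  and mismatched gene/id sets raise typed errors
  (`humsub_*` condition classes) rather than propagating `NaN`.
* A single-bin histogram thresholds at that bin; a peak sitting at the
  range end returns the peak.
* Tie-breaks are deterministic everywhere and stated in the function
  documentation.

Test problem sizes were chosen to exercise the asymptotics while
staying desk-sized: 200 seeded panels for the scan/oracle equivalence,
100 seeded histograms for the threshold oracle, 200 synthetic clusters
for the mixing calibration, and 1000 null simulations for the ANOVA
type-I rate.

## Limitations

* The scan presumes correct alignments and equal-length panels; indels
  and alignment error are out of scope.
* The GO filter is literal string matching; annotation released under
  different capitalisation or renamed terms will not match unless
  `ignore_case` covers it.
* The published genome-scale counts (329 surface proteins, 136 with
  substitutions, dbSNP variability 92–167) depend on database versions
  and are not reproduced here; the corresponding logic is validated by
  recounts on synthetic universes instead.
* Synthetic micrographs are idealised: disk-shaped clusters, uniform
  intensities, uncorrelated Gaussian noise, no uneven illumination, no
  debris, no out-of-focus blur.  Passing image tests demonstrates the
  measurement chain is correct on unambiguous data, not that it is
  robust to the full messiness of real micrographs; in particular the
  single-pixel channel-presence rule inflates mixed fractions when
  noise leaks past the threshold.
* The triangle convention is one defensible reading of the geometric
  method; other implementations differ in smoothing and offset details.
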