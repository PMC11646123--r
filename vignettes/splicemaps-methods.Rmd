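---
title: "Methods: position-dependent motif maps for regulated cassette exons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: position-dependent motif maps for regulated cassette exons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicemaps)
```

## The analysis

Splicing-regulatory RNA-binding proteins (RBPs) act position-dependently:
the same factor activates a cassette exon when bound on one side of it and
represses it when bound on the other. An *RNA map* makes this visible by
comparing, position by position around regulated exons, how often a binding
motif occurs in a *test* set of regulated events versus a *reference* set of
non-regulated events. splicemaps implements this analysis end to end for
cassette (skipped) exons: event classification from differential-splicing
tables, strand-aware sequence extraction, motif scanning, sliding-window
profiles with permutation significance, linked two-motif co-occurrence,
unbiased k-mer discovery, and classification of two-factor co-regulation
and congruence with a reference tissue splicing programme.

The motivating biology is the smooth-muscle splicing programme: RBPMS binds
RNA as a dimer at paired CAC triplets, and RBFOX-family proteins bind
(U)GCAUG; the package ships both motifs as defaults (`motif_rbpms()`,
`motif_rbfox()`), but every analysis accepts arbitrary motifs.

## Event model and thresholds

An event is a cassette exon with flanking introns and constitutive exons,
replicate-level PSI (percent spliced in, in [0, 1]) per condition, a
condition-2-minus-condition-1 `delta_psi`, and an FDR. Tables are read and
written in the rMATS `SE.MATS.JC.txt` column dialect with 0-based half-open
coordinates (no shift on input; one convention throughout avoids off-by-one
drift). When junction counts only are present, PSI is computed as the
length-normalised inclusion ratio. The dialect default corresponds to
junction-count (JC) quantification; exon-body read counting would simply
change the form lengths supplied in the table.

Classification thresholds (`thresholds()`) default to: regulated events at
FDR < 0.05 and |dPSI| >= 0.15 (activated positive, repressed negative);
reference pool at FDR > 0.10 and |dPSI| < 0.10, from which 2000 events are
sampled without replacement. The gap between the 0.10 and 0.15 bands is
deliberate: events in between are neither clearly regulated nor clearly
neutral and are excluded from both sets. A stringent 0.30 cut-off is
provided for functional-impact filtering. Reference sampling is seeded and
the pool is sorted by event id first, so the draw is reproducible across
table orderings; a pool smaller than the requested sample triggers a
warning and uses the whole pool.

### The stand-in differential test

For synthetic tables the package provides `differential_test()`: a
two-sided Welch t-test on logit-transformed replicate PSIs, clamped to
[0.01, 0.99] before the transform (the logit is unbounded at the ends and
replicate PSIs of exactly 0 or 1 are common at finite depth), followed by
Benjamini-Hochberg adjustment across tested events. This is deliberately a
simple, well-calibrated surrogate — real datasets arrive with an FDR from a
dedicated caller, and the surrogate exists so that the synthetic path is
testable end to end. Events with fewer than two replicates or an undefined
PSI in any replicate are flagged untestable (FDR 1), not imputed. With
zero variance in both conditions the P-value is defined as 1 when the
means agree and 0 otherwise.

## Map geometry

The composite axis concatenates eight segments in transcript order: the
3'-most 135 nt of the upstream constitutive exon, 250 nt from each end of
the upstream intron, 135 nt from each cassette-exon end, 250 nt from each
end of the downstream intron, and the 5'-most 135 nt of the downstream
constitutive exon (1540 nt total; all lengths tunable via `map_layout()`).
Intron segments are taken from *both* intron ends so that 5' and 3'
splice-site contexts are each covered — standard RNA-map practice; a
single-end variant is a layout change, not a code change.

Features shorter than the requested lengths are truncated; a feature
hosting two segments (intron or cassette) that is shorter than twice the
requested length is split at its midpoint with no overlap (5' half gets
the floor on odd lengths). Truncated segments stay anchored to their
splice-site end on the axis: 5'-end segments are left-aligned in their
block, 3'-end segments right-aligned. Positions a truncated event does not
reach are simply missing for that event, and every per-position statistic
uses the count of contributing events as its denominator. Bases outside a
chromosome are `N`; soft-masked lowercase is uppercased; ambiguity codes
other than `N` map to `N` with a warning. Minus-strand segments are
reverse-complemented so all downstream analysis sees transcript-sense
sequence.

## Motif model and scanning

Two motif kinds are supported. An *IUPAC word* matches literally with
ambiguity codes; `N` in the scanned sequence never matches. A *gapped
dimer* is two words separated by a bounded spacer: the RBPMS default is
CAC N(1-12) CAC, and **every** (left, right) pair with an admissible gap
yields a hit, so overlapping pairs are all retained at the hit level.
Profiles use the *union* of hit intervals (coverage), which makes them
insensitive to whether overlapping pairs are collapsed — the main reason
coverage was chosen as the primary statistic.

The RBFOX motif "GCAC/TG" is represented as the IUPAC word GCAYG, covering
GCACG and GCATG; the k-mer module handles the concrete form GCATG
independently, so the two interpretations cross-check each other. Scanning
is on transcript-sense sequence only, since extracted segments are already
strand-resolved. Specificity controls are built with `mutate_control()`:
one position of the word forced to a concrete base not matched by the
original letter (default GCAYG -> GCAAG at position 4). A control of the
same length under a comparable base composition matches at a comparable
background rate but carries no biology, so any positional enrichment
surviving the mutation is a red flag for the pipeline, not the motif.

## Window profiles and the permutation null

The per-position statistic is window presence: at axis position p, the
fraction of contributing events whose 31-nt window centred at p — clipped
at the segment boundary, never spanning an exon-intron junction, because a
junction-spanning window would mix the feature classes the map is meant to
separate — contains at least one motif-covered base. Mean per-base coverage
is the obvious alternative; presence was chosen as primary because it is
bounded, interpretable as "fraction of events with the motif here", and
robust to hit-length differences between motif kinds.

Significance at each position is assessed against a label-permutation
null: test and reference events are pooled, `n_perm` (default 1000) random
subsets of size |test| are drawn, and the empirical P-value is
`(1 + #{null coverage >= observed}) / (n_perm + 1)` — the +1 correction
keeps P away from zero, with floor 1/(n_perm+1). A position is flagged
significant when P <= alpha (default 0.05) *and* test coverage exceeds
reference coverage; the one-sided guard matches the question asked
(enrichment on regulated events). P-values are reported per position,
unadjusted, as is conventional for these maps — a contiguous significant
stretch, not an isolated position, is the interpretable signal. An
optional max-statistic familywise correction (`familywise = TRUE`)
compares each observed coverage to the permutation distribution of the
axis-wide maximum, for readers who want a familywise error rate.

Co-occurrence profiles use the same machinery with anchors instead of
hits: two hits on the same segment are *linked* when the gap between their
intervals (zero if they overlap) is at most 25 nt, and an event counts at
a position when the anchor (start of the first motif's hit) of a linked
pair lies in the window. A mutated-control profile is computed in the same
call for the specificity contrast.

## k-mer enrichment and consensus discovery

For an unbiased view, all overlapping 8-mers (windows containing `N`
skipped) are counted in a chosen segment class of the test and reference
sets. The enrichment score of a k-mer is the ratio of its per-window
frequencies with a pseudocount of 0.5 added to both counts (protects
against zero reference counts while barely moving large counts); the null
is again label permutation of event sets with the +1-corrected empirical
P, and k-mers at P < 0.01 are called significant. The score of a shorter
embedded word (e.g. a 5-mer) pools counts over all k-mers containing it —
each genomic occurrence is seen by about k−4 windows in both sets, so the
inflation cancels in the ratio.

Significant 8-mers are clustered: pairwise gapless alignment over all
offsets with at least 5 bases of overlap, distance 1 − matches/overlap at
the best offset, average-linkage hierarchical clustering cut at height
0.4. Each cluster is aligned to its seed (highest enrichment score, ties
broken lexicographically) and summarised as an enrichment-score-weighted
position frequency matrix; the consensus is the IUPAC rendering of the
5-column window with maximal summed information content, where a column's
IUPAC set contains every base reaching at least half the column maximum.
The pseudocount, cut height and weighting are tunables recorded in the
output; they were chosen for stability on desk-scale sets (hundreds of
significant k-mers), not fitted to any particular dataset.

## Co-regulation and congruence

Across a factor over-expression contrast and a co-factor knockdown
contrast, the knockdown dPSI is sign-flipped (`effect_kd = -dpsi_kd`) so a
positive effect always reads "the co-factor promotes inclusion". Events
significant in both contrasts are *coordinate* (categories 1/2 by
direction) when the signs agree and *antagonistic* (3/4, labelled by the
over-expression sign) when they disagree; events significant in one
contrast fall in the single-factor categories (5-8). The numeric category
order is a labelling convention and the labels are explicit strings in the
output, so a different numbering convention is a relabelling, not a
reanalysis. Both contrasts are thresholded with the same
`thresholds()`.

Congruence compares the factor's effect with a reference-tissue-versus-
basal-cell PSI difference: an event significant in both is congruent when
the signs agree, split into congruent-activated/repressed, and discordant
otherwise. A delta of exactly zero cannot clear the magnitude filter; it
is additionally flagged with a warning when the FDRs alone would have made
the event callable.

Gene-set overlap uses the upper-tail hypergeometric probability
P(X >= k), computed in log space. The test universe is always supplied
explicitly — an overlap P-value is meaningless without its universe, and
silently defaulting it invites misuse. The PSI heatmap (`psi_heatmap_matrix()`)
z-scores each event across conditions (zero-variance rows map to zero) and
clusters rows by average-linkage on Euclidean distance.

## The synthetic-data generator

`sim_config()` + `simulate_events()`/`simulate_genome()` generate complete
inputs with truth labels. The generative model is the minimal structure
the downstream analyses assume:

* **PSIs**: replicate PSIs are Beta-distributed around condition means
  (means clamped to [0.02, 0.98]); the concentration default 280 gives a
  PSI standard deviation of about 0.03 at PSI 0.5, a tight but realistic
  replicate spread for deeply sequenced junctions.
* **Counts**: junction totals are Poisson (default mean 150 per
  replicate) and inclusion counts binomial with a form-length adjustment
  (defaults 2 and 1: two inclusion junctions versus one skipping
  junction), so `psi_from_counts()` recovers the PSIs in expectation.
* **Effects**: planted dPSI effects are assigned to *exact* event counts
  (`round(fraction * n)`), default 10% at +0.40 and 15% at −0.40 — a
  minority of events with substantial effects in both directions, with
  the repressed class somewhat larger.
* **Geometry**: cassette exons 80-400 nt, introns 600-3000 nt,
  constitutive exons 150-300 nt, both strands, several chromosomes —
  large enough for full-length map segments while deliberately including
  truncation cases (cassettes shorter than 270 nt).
* **Motif plants**: instances are written in transcript sense at
  controlled offsets in a chosen segment (reverse-complemented into the
  plus-strand genome for minus-strand events) for exact fractions of the
  test group and of the remainder; the default plants the CAC dimer at
  downstream-intron offsets 20-50 in 90% of activated events and 5% of
  others. Planting shares the segment geometry of `extract_regions()`, so
  extraction recovers every instance byte for byte.
* **Cohorts**: contrast-pair and congruence cohorts are generated at the
  summary-statistic level with exact planted category counts, and gene
  sets with an exact planted overlap.

What the generator does **not** emulate: read-level noise and mapping
artefacts, sequence composition structure (splice-site signals, GC
content, repeats), correlation between events of one gene, overdispersion
beyond the beta-binomial, and any dependence between motif presence and
the planted dPSI beyond what is explicitly planted. Passing tests
therefore demonstrate that the *machinery* is correct and calibrated on
data satisfying its assumptions — they do not certify biological
conclusions on real data, where the reference-set choice and composition
biases dominate.

## Numerical choices and determinism

Every stochastic step takes an explicit seed and restores the caller's RNG
state; reruns with one configuration are byte-identical, which the test
suite asserts on file checksums. Ties are broken deterministically
(event-id order for reference sampling, lexicographic k-mer order for
cluster seeds, smaller offset for equal-score alignments). Empirical
P-values use the +1 correction everywhere. The test suite exercises the
map machinery at the full study geometry (200 test versus 2000 reference
events, 1000 permutations, 20-seed null calibration) and scales other
simulations to hundreds or a few thousand events, sizes at which every
planted structure is comfortably detectable in seconds to minutes.

## Known limitations

* RNA maps are built for cassette (SE) events only; other event classes
  are parsed and classified but have no region schema.
* The permutation null resamples event labels; it does not model
  dinucleotide composition differences between test and reference sets (a
  shuffle-based null is a natural extension hook).
* The surrogate differential test assumes approximately independent
  replicates; it is not a substitute for a dedicated caller on real data.
* Hit-level output keeps all overlapping dimer pairs; users counting
  "occurrences" should use coverage or deduplicate explicitly.
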