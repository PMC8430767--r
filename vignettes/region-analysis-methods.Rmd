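---
title: "Methods: region-driven positional co-expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: region-driven positional co-expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Two differential-expression comparisons can agree for two distinct
reasons: the same genes respond in both, or the same chromosomal
neighbourhoods respond while the individual responsive genes differ.  The
second pattern is expected when a stimulus acts on chromatin architecture:
a chromosome territory moved into a more repressive or expressive nuclear
environment drags a contiguous block of genes with it, and which genes of
the block pass a significance filter is partly incidental.  This package
quantifies the region-driven component of inter-comparison agreement.

The procedure per comparison:

1. keep the top *N* genes by absolute log2 fold change (a relative cutoff,
   so comparisons of very different overall intensity stay commensurable);
2. project them onto windows along each chromosome, anchored at
   coordinate 0, of width `window_bp` spaced `step_bp` apart (defaults
   10 Mb / 5 Mb, a 2× oversampling that removes dependence on an arbitrary
   window border: every gene past the first step contributes to exactly
   two windows);
3. keep windows with at least `min_genes` contributors (default 10; 5 in
   subset analyses) and average their fold changes weighted by the per-gene
   average expression value.

Two comparisons are then compared by the Spearman coefficient of their
weighted bin averages over the intersection of retained windows (rank
correlation makes no distributional assumption on the fold-change scale).
The null preserves everything about the data except co-location: one
permutation of the (chromosome, position) labels is drawn over the union
gene list of both tables, a gene present in both receives the same new
location in both, and the full pipeline (selection, binning, correlation)
is re-run.  Gene-level pairing therefore survives the permutation;
correlation driven by shared responsive genes is part of the null
expectation, and only correlation requiring spatial clustering raises the
observed coefficient above it.  The score is the difference between the
actual and the mean permuted coefficient in multiples of the permutation
standard deviation ("sigma difference"), with a two-sided normal tail
probability (0.27% at 3σ) and, when draws are stored, the empirical
permutation p-value `(1 + #{draws ≥ actual}) / (reps + 1)`.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `top_n` | 2000 | genes kept per comparison, by |logFC| |
| `window_bp` | 10,000,000 | window width (bp) |
| `step_bp` | 5,000,000 | window spacing (bp) |
| `min_genes` | 10 (5 in subsets) | minimum contributors per retained bin |
| `reps` | 1000 | location permutations for the null |
| `weighted` | TRUE | expression-weighted bin means |

The weighted mean is `sum(logfc * avg_expr) / sum(avg_expr)` with no
further normalisation; an unweighted mean is available by flag.  Windows
are anchored at coordinate 0 of every chromosome (the anchoring phase is
irrelevant under 2× oversampling, which is its purpose); truncated
terminal windows are retained when they meet `min_genes`.  Spearman ties
receive average ranks and the two-sided p-value uses the large-sample t
approximation; the family for Benjamini–Hochberg adjustment is all
pairwise correlations computed in one run.  With fewer than three shared
bins the coefficient is reported as undefined with a reason code rather
than a number.

Elastic-net fits of the nine structural models use glmnet with mixing
0.5, penalty `lambda = 0.01`, standardised predictors, and no separate
intercept (the quadratic designs carry an explicit constant column; the
indicator designs sum to one per row).  The penalty default is a
deliberate deviation from a unit penalty: on fold-change-scale responses
(|logFC| mostly below 1) a unit penalty soft-thresholds every coefficient
to zero, which defeats the purpose of reading coefficient signs per
chromosome; 0.01 is light regularisation well below the scale of the
effects of interest while still taming the collinear indicator blocks.
Per repetition the rows are split 90:10 at random (the split sequence is
keyed on sorted gene ids, making results invariant to input row order) and
R² is computed on the held-out tenth against the held-out mean, so
negative values are possible and the protocol has no optimistic bias.

## What the generators emulate — and what they do not

`sim_background_pair()` draws per-table logFC independently from Beta(1,1)
mapped affinely to [−0.5, 0.5] — read literally as the uniform background
("centered at 0", maximum ±0.5); other Beta shapes are configurable but
non-default.  Average expression is lognormal(0, 1) and p-values are
rank-based in |logFC| (monotone-decreasing plumbing used only by
threshold operations; no test statistic is modelled).
`plant_strong_pairs()` assigns up to 1000 genes |logFC| in [1, 10] with a
common sign and an absolute between-table difference ≤ 0.1 — conservation
at the gene level with no spatial structure.  `plant_grcr_sites()` plants
up to 500 sites: a centre gene, a half-width drawn from [500 kb, 1.5 Mb]
(spans of 1–3 Mb), all genes within it set to |logFC| in [1, 10] with a
per-site sign shared between tables while the per-gene magnitudes are
independent draws per table — conservation at the region level with no
gene-level magnitude coupling.  Overlapping sites are allowed; later
sites overwrite earlier assignments, and the reported region list gives
drawn, not merged, extents.  Planting never touches positions.

Gene placement is uniform per chromosome (chromosomes drawn proportional
to length).  Real genomes are strongly clustered — gene-rich and
gene-poor regions differ in density by an order of magnitude — and the
binned statistic operates on windows populated by tens of selected genes.
The default synthetic genome therefore keeps the 24-chromosome human
karyotype proportions but scales the total span to about 1 Gb, so that
uniform placement reproduces a realistic per-window occupancy (about 160
genes per 10 Mb window at 16,800 genes, of which about 20 enter a
top-2000 selection) instead of physical base pairs.  Consequences for
interpretation: passing simulation tests demonstrate the statistic's
behaviour under its intended occupancy regime, not robustness to the
sparse-bin regime, and none of the generators model microarray probe
noise, batch effects, correlated expression within pathways, or A/B
compartment structure.

`sim_annotation()` draws centromeres uniformly from the middle third,
Poisson Alu positions (default 3.5e-4 per bp, the human-scale average of
~35 per 100 kb), piecewise-constant replication timing in [−1, 1],
alternating gneg/gpos50 cytobands, tiling ~1 Mb TADs and sparse LADs at a
target coverage (default 0.2).  `sim_hic_table()` emulates the output of
an upstream differential-interaction test: distance-decaying intra
abundance, near-zero inter abundance, uniform null p-values, and planted
small-p pairs anchored in chosen regions.

## Numerical and design choices

* Coordinates are 0-based half-open throughout; readers convert 1-based
  inputs on request and tables are canonically sorted after reading, so
  load order never changes results.
* Chromosome order for the 1D concatenation is fixed: chr1..chr22, chrX,
  chrY; unknown names follow in input order.
* Gene position is the annotated start coordinate (configurable column);
  nothing downstream assumes TSS semantics.
* Top-N ties at the boundary break by lexicographic gene id.
* The location-permutation loop exploits that selection by |logFC| commutes
  with a permutation of location labels: selected gene sets are
  precomputed and only locations are permuted.  This is an exact
  rewriting, guarded by an equivalence test against the naive
  permute-then-select pipeline.
* Arm-end classification uses the outer fifth of each arm measured from
  its telomere; a gene exactly at the arm midpoint is interior, a
  replication index of exactly 0 is "late", and an Alu count of exactly
  the threshold (50) is "poor".  The Alu window is ±50 kb by default
  (published window conventions conflict between ±50 kb and ±100 kb; the
  choice is recorded in the feature attributes and configurable).
* Cytoband stains acen/stalk are excluded from the sign split; TAD/LAD
  two-subset splits are refused with an explicit error because membership
  is too unbalanced to give both subsets enough bins.
* Hi-C pairs: intra/inter classification is by chromosome equality; intra
  pairs need abundance strictly above the threshold before testing, BH runs
  independently per class, and the overlap test counts unique significant
  bins (a bin anchoring several pairs counts once) against all bin-size
  tiles of the genome, one-sided by default because the tested claim is
  directional enrichment.
* Degenerate cases carry flags instead of numbers: zero null SD with a
  non-zero difference reports an infinite sigma; no significant Hi-C bins
  reports p = 1; region bins covering the whole genome make the odds ratio
  undefined.
* Every stochastic operation takes an explicit seed; pipeline stages
  derive seeds from a master seed by a stable hash of the stage name, so
  partial re-runs reproduce full-run numbers.

## Problem sizes used in the shipped checks

The test suite exercises the full pipeline at the study conditions
(16,800 genes, top 2000, 100 repetitions of each simulated scenario) with
200 location permutations per null, and reduced problem sizes (2,000 to
6,000 genes on a three-chromosome genome, 40 to 100 permutations)
elsewhere; the acceptance script averages 100 background-only pairs at
full conditions without nulls.  Where an acceptance property needs a
distributional statement (type-I control, power, calibration), the counts
follow the stated scenario repetitions rather than asymptotic arguments.

## Known limitations

* The permutation exchangeability of the strong-gene model cuts both
  ways: because the actual location assignment is itself one uniform draw
  from the permutation distribution, the sigma score of a gene-pair-driven
  dataset is approximately a standard normal deviate — near zero *on
  average*, but individual datasets can reach |z| of 1–2 without any
  region structure.  Region claims should therefore rest on large sigma
  differences, not on |z| slightly above 1.
* R² values of the structural models are descriptive; no coefficient
  inference (standard errors, confidence intervals) is provided.
* The subset analysis reports bin counts precisely because sparse subsets
  (few retained bins) make coefficients unstable; results with single-digit
  bin counts should not be over-interpreted.
* Hi-C inputs are consumed downstream of an external differential test;
  the package does not model interaction-count statistics itself.
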