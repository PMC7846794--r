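---
title: "Methods: quantifying transient endothelial mesenchymal activation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying transient endothelial mesenchymal activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endmakit)
```

# Scope

`endmakit` analyses time-course single-cell RNA-seq of the infarcted
mouse heart for *endothelial mesenchymal activation* (EndMA): the
transient, reversible acquisition of mesenchymal gene expression by
endothelial cells (ECs) during the first week after injury, with
reversion by day 14. The package covers the full computational chain —
QC, normalization, reporter-positive cell calling, marker-gated
classification and kinetics, cell-cycle scoring, zero-inflated
differential expression, enrichment scoring, a ligand–receptor
permutation network, and a clonal-expansion statistic — and ships a
synthetic-data generator whose ground truth makes every stage testable.

# Quality control and normalization

`filter_cells()` retains cells with at least `min_genes = 200` detected
genes, a mitochondrial UMI fraction of at most `max_mito = 0.10`
(mitochondrial genes recognised by the mouse `mt-` prefix, overridable),
and total UMI and detected-gene counts inside the per-sample percentile
band between the `lower_pct = 0.01` and `1 - upper_pct = 0.95` sample
quantiles. Three numerical choices deserve note:

* the band is **closed** (boundary values kept), so a degenerate sample
  of identical cells is retained in full rather than annihilated;
* UMI and gene-count trimming are applied **independently** and a cell
  is excluded if it violates either (the union of exclusions); whether
  the two filters should instead be applied jointly is not decidable
  from the analysis description, so the choice is explicit and recorded
  per cell in the QC report;
* percentile bands are computed **per sample** (one sample per
  timepoint here), since library depth differs between samples.

`lognormalize()` computes `ln(1 + count / cell_total × 10⁴)` and
per-gene z-scores clipped at ±10. Clipping bounds the influence of
extreme cells; for genes whose z-scores touch the clip the scaled row is
no longer exactly unit-variance, which is intended. Constant genes scale
to 0; zero-total cells get all-zero values and are flagged.

# Reporter-positive cell calling

Lineage tracing labels ECs with a membrane reporter (tdTomato switching
to EGFP upon recombination). Sequenced EGFP counts mix three
populations: exact zeros, spurious low "ambient" counts, and genuinely
recombined cells. `call_reporter_positive()` estimates a Gaussian kernel
density of per-cell normalized EGFP on a 512-point grid over
`[0, max(expr)]` and places the per-sample threshold at the local
minimum directly left of the rightmost mode carrying at least
`min_mode_mass = 0.01` of the cells.

Design choices:

* **Zeros enter the density by default** (`include_zeros = TRUE`). The
  zero spike anchors the lower mode; without it, a sample whose positive
  values are unimodal has no interior minimum and no threshold could
  ever be found even in the textbook 90%-zero / 10%-high mixture. With
  `include_zeros = FALSE` the threshold becomes exactly invariant to
  adding zero-expression cells, which is occasionally useful and is the
  configuration under which that invariance is asserted in the tests.
* **Bandwidth** (`"auto"`): Silverman's rule computed on the *nonzero*
  values. Computed on all values, the zero spike collapses the rule's
  spread estimate and the resulting narrow kernel fragments the high
  mode into spurious sub-modes.
* **Shallow-dip merging** (`dip_frac = 0.9`): a local minimum separates
  two modes only if the density there falls below 0.9 times both
  neighbouring peaks; otherwise it is a finite-sample wiggle on a mode's
  flank and is merged. Together with `min_mode_mass` this makes the mode
  search robust at realistic cell numbers.
* If no qualifying structure remains — all cells zero, a strictly
  unimodal distribution, or no genuine lower population below the
  candidate cut — the threshold is `+Inf` and every cell is negative.
  This reproduces the expected behaviour on an uninduced (no-tamoxifen)
  sample: essentially zero positives.

# EC gating, EndMA classification and kinetics

ECs are gated as raw UMI > 0 for both `Cdh5` and `Pecam1`
(`subset_ec()`); for integer counts this is identical to the UMI ≥ 1
convention used by all expressing-fraction summaries, and the package
standardizes on raw-count thresholds for gating. `classify_endma()`
calls a gated cell EndMA⁺ iff it has UMI ≥ 1 for every positive marker
(default `Serpine1` and `Fn1`).

The kinetics summaries are deliberately simple statistics with fixed
conventions:

* `fraction_expressing()`: per-timepoint fraction of cells at UMI ≥ 1
  for all (or any) listed genes.
* `zscore_kinetics()`: per gene, the per-timepoint mean log-normalized
  expression is z-scored **across timepoints** with the sample (n−1)
  SD — genes constant across timepoints score 0 — then averaged over
  the panel. The default endothelial panel of four is `Cdh5`, `Pecam1`,
  `Vwf`, `Cldn5`; the exact panel is configurable since marker panels
  are a reporting choice, not an algorithm.
* `foldchange_to_baseline()`: `(mean + pc)/(mean_baseline + pc)` with
  `pc = 1e-9`, on log-normalized means by default (raw means by flag).
  Two zero means give pc/pc = 1, a neutral fold change.
* `quadrant_analysis()`: a cell is a "strong" expressor if its value
  exceeds the median of that marker's nonzero values pooled **across
  all timepoints** — one fixed box for every panel so percentages are
  comparable over time.

# Cell-cycle scoring

`score_gene_set()` is a bin-matched module score: genes are binned into
`n_bins = 24` equal-frequency bins by mean expression; for each member
gene, `n_ctrl = 100` control genes are sampled (seeded, with
replacement) from its bin; the score is the mean expression of the set
minus that of the control multiset. `assign_phase()` then labels a cell
S if the S score exceeds both the G2/M score and zero, G2/M if the G2/M
score is at least the S score and positive, else G1 (ties go to G2/M).
S and G2/M gene lists ship as mouse orthologs of the canonical human
phase markers and are overridable.

One adjustment matters on compact gene universes: when the scored
program is a substantial fraction of its expression bins (here ~95
cycle genes among ~1,260 simulated genes), bin-matched controls would be
drawn largely from the program itself and the score collapses toward
zero. `score_cell_cycle()` therefore excludes the union of both phase
lists from the control pools (`ctrl_exclude`), which emulates the
genome-scale regime where the program is a negligible bin fraction. On
genome-scale data the exclusion is a no-op in expectation.

`phase_independence_test()` is the chi-squared test of independence
with the Yates continuity correction applied cell-wise,
`Σ (max(|O−E|−0.5, 0))² / E` with `(r−1)(c−1)` degrees of freedom. For
2×2 tables this is the classical corrected test; applying the
correction cell-wise extends it to the phases × timepoints tables the
analysis uses, and a flag disables it.

# Zero-inflated differential expression

`bimod_lrt()` models each group as a point mass at zero with
probability `1 − π` plus a normal on the nonzero values, and tests
shared `(π, μ)` against group-specific values with a common variance;
the statistic `2(ℓ₁ − ℓ₀)` is referred to χ² with **df = 2** (one
degree for the detection rate, one for the positive mean; the common
variance is a nuisance parameter re-estimated under each model).
Degenerate inputs are resolved explicitly: an all-zero group
contributes through the detection component alone; if the pooled
nonzero values are constant the normal component cancels between the
nested models and the test reduces to its detection part; two all-zero
groups give statistic 0, p 1. A grid-search likelihood oracle in the
test suite guards the closed-form implementation to 10⁻³, and the
test's type-I error at α = 0.05 is checked to lie in [0.03, 0.07] over
2,000 null replicates.

`log_fold_change()` works on de-logged means (`mean(expm1(x))`) with
pseudocount 1, matching the convention of mainstream single-cell
software; `de_bimod()` applies Bonferroni over the genes actually
tested.

# Enrichment scoring

`enrich_terms()` ranks terms by a combined score `ln(p) × z`, where `p`
is the Fisher exact overlap p-value against the background universe and
`z` is the deviation of the term's rank from its expected rank. The
original software calibrates expected ranks on precomputed tables that
are not redistributable; the package estimates them by `n_null = 100`
seeded random queries of the same size, and documents that the two
calibrations need not coincide numerically. The background defaults to
all detected genes; an integer `background` pads the library union with
inert genes to the requested size.

`fisher_exact()` computes the two-sided p by summing hypergeometric
probabilities not exceeding the observed table's, with the conventional
`1 + 1e-7` relative tolerance for floating-point ties; the test suite
checks it exhaustively against a log-factorial enumeration for all 2×2
tables with grand total ≤ 30.

# Ligand–receptor network

`build_lr_graph()` assembles the four-layer weighted directed graph:
source cell types → ligands → receptors → target cell types. An edge
source→ligand exists iff the ligand's mean expression in the source
reaches `min_expr = 0.1` (mean log-normalized units) and carries the
ligand's fold-change; receptor→target edges symmetrically;
ligand→receptor edges carry the catalog association score. The
aggregation — path weight = product of the three edge weights, summed
over all catalog pairs connecting a source–target pair — is the minimal
reading of "weighted directed graph with per-edge weights" and is
isolated in one function so an alternative pooling can be substituted.
Fold-changes may be computed per cell type versus the rest (default) or
versus a baseline condition within each type; the original analysis
does not state which was used, so both are supported.

`permutation_significance()` re-pairs ligands with receptors uniformly
at random (scores stay attached to their pair slot, preserving the
weight marginals), recomputes all aggregates per permutation, and uses
the add-one estimator `p = (1 + #{perm ≥ obs})/(n_perm + 1)` with BH
correction across source–target pairs (`n_perm = 100,000`,
`α = 0.01` by default; tests scale `n_perm` down to 2,000).

A structural property of this permutation scheme is worth recording: a
**single** planted ligand–receptor pair cannot reach very small
p-values, because any permutation that happens to re-create the planted
pairing (probability `1/n_pairs` per permutation) reproduces the
observed aggregate up to symmetric noise, flooring `p` near
`1/(2 n_pairs)`. Significant source–target connections therefore
reflect **coordinated programs** — several ligands elevated in the
source with their receptors elevated in the target — and the package's
recovery experiment plants exactly that (8 high-association pairs,
fold-change 3, in an 80-pair catalog).

# Clonal-expansion statistic

Multicolor (RFP/YFP/GFP) reporter images are quantified as counts per
animal over 5 images × 6 equal areas. `flag_clonal_areas()` flags an
area as clonally expanded if, for any fluorophore, its count exceeds
the animal's mean plus twice the sample SD over that animal's areas
(strict inequality; constant counts flag nothing). The underlying
verbal rule ("more than two times the standard deviation of the animal
mean") admits a second literal reading, `count > 2·SD`, selectable via
`rule = "two_sd"`. `compare_groups()` compares flagged-area incidence
between two groups with the Fisher exact test on areas (not images) and
reports the percent reduction with a bootstrap SD over animals.

# The synthetic-data generator

`simulate_dataset()` emulates the seven-timepoint design (`Hom`, `d1`,
`d3`, `d5`, `d7`, `d14`, `d28`) with four cell types (EC, fibroblast,
monocyte, SMC). Counts are negative binomial per gene and program
(size 2 baseline, 3 for induced programs); library size is a lognormal
per-cell factor (σ = 0.3) so percentile QC has something to trim. The
default schedules encode the transient biology: the EndMA fraction of
ECs rises from 2% at homeostasis to 45% at days 3–5 and reverts to 5%
by day 14; cycling peaks at day 3 (30% of ECs); immune cells flood in
at days 1–7. Mean-expression levels (e.g. identity markers ≈ 3 UMI,
`Cdh5`/`Pecam1` ≈ 10, mesenchymal genes in activated cells ≈ 15,
EGFP ≈ 20 in labeled cells) were chosen once as realistic magnitudes
that give the same qualitative separability real data shows —
detectable gates, a bimodal reporter, separable cycle phases — and are
all configurable. Configured fractions are realized **exactly**
(largest-remainder apportionment and exact subset sizes), so
ground-truth frequencies equal the schedules up to rounding and
recovery experiments measure classification error, not generator
sampling noise. `gene_params` plus the per-cell truth labels fully
determine every cell's generative distribution (no hidden state), and
a single seed drives all substreams.

What the generator does **not** emulate: doublets, ambient RNA beyond
the reporter, batch effects, gene–gene correlation beyond program
structure, read-level noise, and realistic transcriptome-wide mean
distributions. Passing recovery tests therefore demonstrates that the
implementations are faithful to their definitions and calibrated under
their stated noise model — not that the thresholds are optimal for any
particular real dataset.

Trajectory-state labels (1–5, ECs only) are *assigned* from the truth
flags (mesenchymal program → state 4, cycling → state 5, remainder
spread over quiescent/inflammatory states) because trajectory inference
itself is out of scope; they exist so downstream consumers have a
state-shaped column to exercise.

# Problem sizes and runtime choices

The shipped experiments use sizes chosen to make the statistics
well-conditioned: recovery runs use 500 ECs per timepoint (binomial SE
≈ 0.022 at the peak fraction), the phase-recovery experiment uses
day-3-like cycling (30%) where phase margins are well separated, null
calibrations use 2,000 LRT replicates, 50 network datasets × 500
permutations, 20 planted-network runs × 2,000 permutations, and 500
clone-table seeds. The pipeline determinism check runs 300 cells per
timepoint with 200 permutations. These sizes keep the full suite and
the acceptance script in the minutes range while leaving all acceptance
margins dominated by method behaviour rather than sampling noise.

# Known limitations

* The reporter threshold is a 1-D density heuristic; heavily
  overlapping ambient and recombined modes (separation ≲ 2 bandwidths)
  cannot be split reliably, and `dip_frac`/`min_mode_mass` are
  heuristic guards, not estimators.
* The bimodal LRT uses plug-in maximum likelihood with χ²₂ asymptotics;
  at very small group sizes its size deviates from nominal (the suite
  checks n = 100 per group).
* Enrichment z-scores depend on the resampled rank calibration and are
  seeded but Monte-Carlo noisy at `n_null = 100`.
* The network permutation test is calibrated for exchangeable
  fold-changes; systematic depth differences between cell types should
  be removed by normalization before profiling.
* `compare_groups()` bootstrap resamples animals, which is coarse for
  very few animals per group (SDs are then wide and should be read as
  such).
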