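# endmakit

Tools for analysing transient **endothelial mesenchymal activation
(EndMA)** in time-course single-cell RNA-seq of the injured mouse heart.
After myocardial infarction, endothelial cells (ECs) transiently acquire
mesenchymal gene expression (*Col1a1*, *Col3a1*, *Serpine1*, *Fn1*, ...)
during the first week and revert by day 14 — a reversible activation
rather than a full endothelial-to-mesenchymal transition. `endmakit`
implements the complete computational pipeline for characterising this
phenomenon, together with a seeded synthetic-data generator with ground
truth, so every stage is testable without access to the original animal
datasets.

## What it implements

| Stage | Function(s) | Method |
|---|---|---|
| Quality control | `filter_cells()` | ≥ 200 detected genes, mitochondrial UMI ≤ 10%, per-sample 1%/5% depth-percentile bands |
| Normalization | `lognormalize()` | `ln(1 + count/total × 10⁴)`, per-gene z-scores clipped at ±10 |
| Reporter calling | `call_reporter_positive()` | dynamic per-sample cutoff at the local minimum of the EGFP expression density |
| EC gating / EndMA | `subset_ec()`, `classify_endma()` | `Cdh5⁺/Pecam1⁺` (UMI > 0); EndMA⁺ iff `Serpine1 ≥ 1` and `Fn1 ≥ 1` |
| Kinetics | `fraction_expressing()`, `zscore_kinetics()`, `foldchange_to_baseline()`, `quadrant_analysis()` | UMI ≥ 1 fractions, marker-set mean z-scores, fold-change to homeostasis, top-50%-of-nonzero quadrants |
| Cell cycle | `score_gene_set()`, `assign_phase()`, `phase_independence_test()` | bin-matched module scores; phases × timepoints chi-squared with Yates correction |
| Differential expression | `bimod_lrt()`, `de_bimod()` | zero-inflated bimodal likelihood-ratio test (df = 2), Bonferroni correction |
| Enrichment | `enrich_terms()`, `fisher_exact()` | combined score = ln(p) × z of rank deviation, Fisher exact overlap p |
| Cell–cell communication | `build_lr_graph()`, `permutation_significance()` | four-layer source→ligand→receptor→target graph; 100,000-permutation significance with BH correction |
| Clonal expansion | `flag_clonal_areas()`, `compare_groups()` | per-animal mean + 2·SD area rule; Fisher exact group comparison |
| Synthetic data | `simulate_dataset()`, `simulate_lr_catalog()`, `simulate_clone_counts()` | negative-binomial UMI counts over a 7-timepoint design with full ground truth |

The core statistic for differential expression models expression in each
group as a point mass at zero with probability `1 − π` plus a normal
component on the nonzero values; the likelihood-ratio statistic
`2(ℓ₁ − ℓ₀)` for group-specific `(π, μ)` against shared values (common
variance) is referred to χ² with 2 df. The ligand–receptor statistic for
a source–target pair aggregates `FC_ligand × association score ×
FC_receptor` over all catalog pairs and compares it with re-paired
(permuted) catalogs: `p = (1 + #{perm ≥ obs}) / (n_perm + 1)`.

## Worked example

```r
library(endmakit)

sim  <- simulate_dataset(sim_config(n_cells_per_timepoint = 1000, seed = 3))
norm <- lognormalize(filter_cells(sim$dataset))
ec   <- subset_ec(norm)
lab  <- classify_endma(ec)
tp   <- ec$data$cell_meta$timepoint
round(vapply(unique(tp), function(t) mean(lab[tp == t] == "EndMA+"),
             numeric(1)), 3)
#>   Hom    d1    d3    d5    d7   d14   d28
#> 0.009 0.160 0.419 0.420 0.302 0.052 0.016
```

The recovered EndMA⁺ fraction among `Cdh5⁺/Pecam1⁺` cells reproduces the
planted transient program: ~1% at homeostasis, a ~42% peak at days 3–5,
and reversion to ~5% by day 14. Continuing with the same objects:

```r
de <- de_bimod(ec, lab == "EndMA+")
head(de[de$log_fc > 0, c("gene", "log_fc", "p_bonferroni")], 3)
#>       gene   log_fc  p_bonferroni
#> 1      Fn1 4.908894 1.160868e-280
#> 2    Postn 4.573055 1.042375e-272
#> 3 Serpine1 4.467512 3.507484e-270
```

the mesenchymal program genes dominate the EndMA⁺ versus EndMA⁻
comparison, with strongly positive natural-log fold changes.
`run_pipeline(pipeline_config(out_dir = "out", seed = 1))` executes all
stages end to end and writes one tidy CSV per stage.

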