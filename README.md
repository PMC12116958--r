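# glycodyn

Single-cell multi-modal experiments can now read out, for the same cells,
the transcriptome, the *dynamic* transcriptome (metabolically labeled new
vs pre-existing RNA), and cell-surface glycosylation quantified through
sequencing of oligonucleotide tags conjugated to fucose residues at
LacNAc glycosylation sites. `glycodyn` implements the bespoke
computational steps such studies need between the sequencer and the
biology, as composable, tested R functions:

- **Tag-library demultiplexing** — cell barcode/UMI extraction from R1,
  Hamming-1 barcode correction against a whitelist, positional extraction
  of the 15-bp tag from R2 (poly-A tail ignored), tag validation at
  Hamming distance < 2, and UMI deduplication into a cell × tag count
  matrix with a full read-fate tally.
- **Glycosylation scoring** — centered log-ratio (CLR) normalization per
  sample, a median split into glycosylation-high/low cells, and
  top/bottom-20% strata by nearest-rank quantiles.
- **RNA dynamics** — validation of new/old/total count-matrix triples
  (`new + old = total`, element-wise) and the new-to-total RNA ratio
  (NTR), per cell and aggregated per cluster.
- **Expression statistics** — the standard single-cell QC filters
  (gene-count, top-2% gene/UMI percentile, 20% mitochondrial content,
  5-cell gene floor), total-count log-normalization, and a from-scratch
  Wilcoxon rank-sum differential-expression procedure with
  expression-fraction (>10%), log-fold-change (>0.25, natural log) and
  Bonferroni filters.
- **Staging** — pseudo-bulk cluster profiles, the between-cluster
  Spearman correlation matrix, and an average-linkage cut into three
  differentiation stages.
- **Synthetic data** — a generator that emulates a six-timepoint
  (D0–D10), 18-cluster, three-stage differentiation experiment with full
  ground truth (tag reads with configurable per-base errors, tri-count
  matrices by binomial thinning, planted QC violations and planted
  fold changes), so every stage of the pipeline is testable end to end.

## The quantities at the core

For a cell with tag counts \(x_1, \dots, x_k\) the CLR is
\( \mathrm{clr}(x)_i = \ln(x_i + c) - \tfrac1k \sum_j \ln(x_j + c) \)
with pseudocount \(c = 1\); with a single tag species the same transform
is applied across the cells of a sample to \(\ln(\text{total}+1)\).
The per-cell NTR is the ratio of sums
\( \mathrm{NTR}_c = \sum_g n_{cg} / \sum_g t_{cg} \) over the new and
total matrices. Differential expression between groups \(A\) and \(B\)
uses the Mann–Whitney/Wilcoxon rank-sum test (exact enumeration for
pooled sizes ≤ 12, otherwise normal approximation with tie and
continuity corrections), the average log fold change
\( \ln(\overline{\mathrm{expm1}(x_A)} + \varepsilon) -
   \ln(\overline{\mathrm{expm1}(x_B)} + \varepsilon) \),
and Bonferroni correction over the genes actually tested. Stages are the
\(k = 3\) groups obtained by average-linkage clustering of clusters at
distance \(1 - \rho\), with \(\rho\) the Spearman correlation of
pseudo-bulk profiles.

## Worked example

An end-to-end run on the default synthetic experiment (1,800 cells, 18
clusters, 4 tag species, 600 genes):

```r
library(glycodyn)
cfg <- sim_config(seed = 7)
pl  <- run_pipeline(cfg, n_boot = 500)
pl
#> <glyco_pipeline> 1800 cells, 18 clusters
#>   demux valid reads: 58939 / 58939
#>   stages (glyco): stage2 > stage3 > stage1 [bootstrap support 1.000]
#>   stages (NTR):   stage3 > stage1 > stage2 [bootstrap support 1.000]
pl$stage_summary
#> # A tibble: 3 × 4
#>   stage n_cells   glyco   ntr
#>   <int>   <int>   <dbl> <dbl>
#> 1     1     583 -0.758  0.450
#> 2     2     573  0.685  0.150
#> 3     3     644  0.0770 0.600
```

With error-free reads every read demultiplexes (`valid 58939/58939`) and
the cell × tag matrix equals the simulation's ground truth exactly. The
per-stage mean glycosylation score is highest in stage 2 and the NTR
highest in stage 3 and lowest in stage 2 — the configured biology of the
generator, recovered through the full demultiplex → CLR → NTR → staging
chain, with every one of 500 seeded bootstrap resamples reproducing both
orderings. The recovered stage NTRs (0.450, 0.150, 0.600) match the
generator's per-stage labeling probabilities.

Differential expression with planted truth (50 two-fold genes among
2,000; 200 cells per group):

```r
deg_cfg <- sim_config(n_samples = 3, clusters_per_sample = 1,
                      n_cells_per_sample = 200, n_genes = 2000,
                      cluster_mix = 1, marker_frac = 0,
                      cluster_marker_frac = 0,
                      ntr_per_stage = c(0.3, 0.3, 0.3),
                      n_deg_genes = 50, deg_fold_change = 2,
                      deg_groups = list(a = 1, b = 2), seed = 7)
sim <- simulate_tri_counts(deg_cfg)
deg <- find_degs(lognormalize(sim$total),
                 sim$cells$barcode[sim$cells$cluster == 1],
                 sim$cells$barcode[sim$cells$cluster == 2])
glance(deg)
#> # A tibble: 1 × 3
#>   n_tested n_significant alpha
#>      <int>         <int> <dbl>
#> 1      272            50  0.05
```

All 50 significant genes are the 50 planted ones (|logFC| ≈ ln 2 ≈ 0.8,
in both directions, Bonferroni-adjusted p ≪ 0.05).

Result objects come with `tidy()`/`glance()` methods and
`autoplot()`/`plot_*()` views (`plot_stage_corr()` for the correlation
heatmap, `autoplot(deg)` for the volcano plot, `autoplot(pl)` for the
per-stage summary).

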