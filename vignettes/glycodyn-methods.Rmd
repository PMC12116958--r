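---
title: "Methods: tag demultiplexing, glycosylation scoring, RNA dynamics and staging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tag demultiplexing, glycosylation scoring, RNA dynamics and staging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycodyn)
```

`glycodyn` covers the computational path from raw glycosylation-tag
library reads and new/old/total count matrices to an integrated per-stage
summary of glycosylation and transcriptional activity. This vignette
explains each procedure, its assumptions, the tunable parameters, and
the design decisions taken where the methodology was genuinely open.

## Tag-library demultiplexing

The assay attaches, to cell-surface LacNAc glycosylation sites, fucose
residues carrying an oligonucleotide with a PCR handle, a known 15-bp
sequence, and a poly-A stretch. After droplet capture, R1 carries the
cell barcode and UMI and R2 the tag construct, so counting distinct UMIs
per (cell, tag) estimates per-cell glycosylation-site abundance.

Processing of each read pair:

1. **Barcode/UMI extraction** (`extract_barcode_umi()`): positional
   slicing of R1 — barcode `[0, barcode_len)`, UMI
   `[barcode_len, barcode_len + umi_len)` (0-based, half-open
   throughout). Bead chemistries differ, so both lengths are policy
   parameters (`barcode_policy()`, defaults 16 and 12) rather than
   constants. Reads shorter than the policy are skipped and tallied.
2. **Barcode correction** (`correct_barcode()`): exact whitelist match,
   else the unique whitelist entry at Hamming distance 1, else
   unassigned. This is the common droplet-barcode convention; without a
   whitelist the demultiplexer keeps every observed barcode verbatim
   (permissive mode).
3. **Tag extraction and validation** (`match_tag()`): the 15-mer at
   `tag_offset` on R2 is compared against the tag whitelist; a tag at
   Hamming distance less than 2 from a unique whitelist entry is valid.
   `N` mismatches every base (including `N`), so one `N` still permits a
   distance-1 match while two or more can never validate. The poly-A
   tail lies after the tag, so positional extraction makes trimming
   unnecessary; `trim_polya()` is provided for constructs that need it
   (suffix from the first run of ≥ 6 A's).
4. **UMI counting**: a cell's tag count increments once per distinct
   (corrected barcode, UMI, tag) triple; duplicate reads collapse. UMI
   collisions are not error-corrected — deduplication is exact-sequence.

Matching uses a precomputed Hamming-1 neighborhood hash of the whitelist
(each whitelist entry plus all single-position substitutions over
A/C/G/T/N, collisions marked ambiguous); the contract is identical to
brute-force scanning, which the test suite verifies by enumeration.
`demultiplex_fastq()` streams files in chunks (default 100,000 records)
so inputs need not fit in memory, and the report partitions every read
exactly: `reads_seen = valid + invalid + ambiguous + unassigned +
skipped`.

## Glycosylation scoring

Tag counts are compositional, so normalization uses the centered
log-ratio with a pseudocount of 1 before the log (counts contain zeros;
the pseudocount is configurable; natural logarithm throughout). Two
modes exist because the CLR is degenerate for a single tag species:

- `per_tag`: the textbook per-cell CLR across tag species; each cell's
  values sum to zero.
- `total` (default, and the score used downstream): the CLR applied
  across the cells of a sample to the per-cell total,
  `ln(total + 1)` centered by the within-sample mean. This is the
  standard choice for single-species tag data and reduces the per-sample
  normalization to a within-sample centered log count.

Stratification happens within each sample on the normalized score:
`median_split()` labels cells strictly above the median high, ties low
(deterministic; the direction is a documented convention), and
`quantile_strata()` implements top/bottom-20% strata with nearest-rank
order statistics: the low cut is the value at rank `ceiling(q n)` and
the high cut at rank `n - ceiling(q n) + 1`, so distinct values give
exactly `ceiling(q n)` cells per extreme stratum. Cells qualifying for
both extremes under heavy ties fall to `mid` with a warning. Both labels
are invariant under strictly increasing transforms of the score. A flag
allows stratifying on raw totals instead; per-cluster aggregation
(`glyco_cluster_summary()`) defaults to the mean, with median exposed,
since the aggregator behind cluster-level glycosylation summaries is not
uniquely determined.

## New-to-total RNA ratio

Metabolic labeling decomposes each cell × gene count into new (labeled
window) and old transcripts, `new + old = total` exactly.
`validate_tri()` enforces this conservation (and derives `old` when
absent); violations are reported with the offending cell and gene. The
NTR is defined here as the per-cell ratio of sums,
`sum(new) / sum(total)`, rather than a mean of per-gene ratios — the
ratio of sums is well-defined for zero-count genes and weights genes by
evidence. The definition is an interpretation (no algebraic definition
is in common circulation) and is stated as such. Cells with zero total
counts are flagged missing, never imputed as 0, and excluded from
cluster aggregates. The cluster aggregator defaults to the mean over
cells, with median and pooled (`sum(new)/sum(total)` within the
cluster) variants; pooled and mean agree exactly when all cells in a
cluster have equal totals.

## QC, normalization and differential expression

`qc_filter()` applies four rules in a fixed order: (1) cells with fewer
than 200 detected genes or a detected-gene count in the top 2% are
removed; (2) cells with a top-2% total UMI count are removed; (3) cells
above 20% mitochondrial content (genes prefixed `MT-` by default,
overridable) are removed; (4) genes expressed in fewer than 5 retained
cells are removed. Percentile cuts use the nearest-rank order statistic
at rank `ceiling(0.98 n)` over the cells entering that rule, removing
cells strictly above the cut — strict inequality at the boundary is a
deliberate choice where the convention is ambiguous. Because the
percentile rules are relative, the filter is not idempotent: rerunning
it on its own output can remove another top slice; the absolute rules
are idempotent. `lognormalize()` is
`ln(1 + 10^4 x / total)` per cell.

`find_degs()` mirrors the widespread rank-sum marker procedure: per
gene, the fraction of expressing cells per group and the average log
fold change on de-logged normalized means
(`eps = 1e-9`, natural log — the base matters for the 0.25 threshold
and is chosen to match the convention of the commonly cited
implementation). Genes pass to testing only if expressed in more than
10% of either group's cells and `|logFC| > 0.25`; the Bonferroni
multiplier is the number of genes actually tested (a flag switches to
all genes). Significance requires all three: adjusted p below 0.05,
`|logFC| > 0.25`, expression fraction above 10%.

The Wilcoxon rank-sum test itself is implemented in the package: exact
enumeration of all group assignments for pooled sizes ≤ 12 (two-sided
`p = min(1, 2 min(P(W ≤ w), P(W ≥ w)))`, midranks for ties) and the
normal approximation with tie correction and 0.5 continuity correction
otherwise. The tests verify the exact path against an independent
bitmask-enumeration oracle and the approximate path against the exact
tail and against `stats::wilcox.test`.

## Staging by pseudo-bulk Spearman correlation

`pseudobulk()` averages normalized expression per cluster;
`spearman_matrix()` computes between-cluster Spearman correlations
(average ranks for ties, constant profiles flagged `NA`);
`partition_stages()` runs average-linkage agglomerative clustering on
`1 - ρ` and cuts at `k = 3`. The grouping method behind published
correlation-heatmap stagings is typically not stated; average linkage on
correlation distance is the simplest faithful, reproducible surrogate,
with the linkage method exposed (`complete`, etc.) for sensitivity
checks. Stage ids are relabeled by first appearance so the output is
deterministic; comparisons against reference labelings should be made up
to label permutation (adjusted Rand index). Pseudo-bulk is computed on
log-normalized values by default (matching the matrix such correlations
are plausibly computed on); raw-count profiles are accepted by the same
functions.

## The synthetic experiment

The generator emulates a six-timepoint differentiation experiment
(samples D0–D10, 300 cells each by default) with 18 clusters in three
stages and two planted biological signals: per-stage glycosylation-tag
abundance ordered stage 2 > stage 3 > stage 1 (negative-binomial means
10/60/30 tag UMIs per cell for stages 1/2/3) and per-stage NTR ordered
stage 3 > stage 1 > stage 2 (labeling probabilities 0.45/0.15/0.60).
Counts are negative binomial with dispersion 0.5 — typical UMI
over-dispersion — since no generative model is prescribed by the assay;
new counts arise by binomial thinning of totals, so `new + old = total`
holds by construction.

Design choices worth knowing:

- **Clusters span samples.** Each sample draws 60% of its cells from the
  clusters of its own stage and 20% from each other stage, as in real
  timepoint experiments where cluster membership overlaps timepoints.
  This matters for normalization: the glycosylation CLR centers within
  sample, so if each sample contained only its own stage's clusters the
  centering would erase all between-stage signal. With overlapping
  membership the within-sample contrasts survive centering and the
  stage ordering is recoverable — and with `cluster_mix = 1` the
  degenerate design is available for tests that need it.
- **Stage programs.** Ten percent of genes per stage form a
  marker program (3-fold elevated), plus a small 2%/1.5-fold
  per-cluster program, so pseudo-bulk profiles correlate by stage but
  clusters remain distinguishable.
- **Balanced DEG planting.** Planted fold changes alternate direction
  between the two contrast groups and avoid the top expression decile.
  A one-sided tilt on abundant genes shifts library sizes, and after
  total-count normalization every *other* gene becomes genuinely
  differentially expressed — a compositional artifact that would be
  detected, correctly, as "false" positives. Balanced planting keeps
  non-planted genes truly null, which is what a false-positive-rate
  check needs.
- **Tag whitelist.** Four random 15-mers at pairwise Hamming distance
  ≥ 4, generated from the seed (real kit sequences are proprietary).
  Distance ≥ 4 guarantees single-error reads match a unique tag;
  whitelists violating it are rejected. Every base of an emitted tag
  substitutes independently with `tag_error_rate` (substitutions never
  reproduce the original base), so the fraction of reads at distance
  ≤ 1 follows the closed form `(1-p)^15 + 15 p (1-p)^14` exactly —
  the calibration the tests check at p = 0.01 against 3 binomial
  standard deviations. Read order is shuffled deterministically so
  demultiplexing cannot exploit grouping.
- **QC fixture.** `simulate_expression_for_qc()` makes all baseline
  cells share one detected-gene count and one total, so the relative
  top-2% rules have nothing to remove beyond the planted cells and each
  planted cell violates exactly one rule; planted rare genes sit one
  cell below the 5-cell floor. The truth table is exact by
  construction.

What the generator does **not** emulate: ambient RNA, doublets, UMI
sequencing errors, incomplete metabolic-label detection (the NTR is
treated as the direct labeling probability — detection chemistry would
shrink observed NTRs toward 0 but preserve orderings), T→C conversion
calling, batch effects, and gene–gene correlation beyond the block
programs. Passing tests therefore demonstrate the correctness of the
implemented procedures under realistic count noise, not robustness to
every artifact of real libraries.

## Determinism, problem sizes and numerics

All randomness flows from one integer seed per configuration; generators
save and restore the session RNG state. Identical configurations give
byte-identical FASTQ and TSV artifacts, and each pipeline run is stamped
with its seed and a configuration hash. The test and acceptance runs use
moderate sizes chosen to exercise the statistics properly: ~2,000 cells
at ~50 tag UMIs/cell for demultiplexing exactness, ~100,000 reads for
error calibration, 1,800 cells / 600 genes for the end-to-end staging
and ordering checks (with 1,000 bootstrap resamples for ordering
support), and 2,000 genes / 200 cells per group with 50 planted 2-fold
genes for differential expression.

Numerical conventions: natural logarithm everywhere; CLR row sums are
zero to floating tolerance (checked at 1e-9); correlation matrices are
symmetric with unit diagonal; `hclust` ties resolve deterministically
from the distance matrix; quantile and percentile rules use nearest-rank
order statistics, never interpolation, so every cut is a value observed
in the data.

## Known limitations

- The three-stage cut assumes the correlation structure actually has
  `k` groups; `partition_stages()` will cut any tree into `k` groups
  regardless of support. Inspect the correlation heatmap
  (`plot_stage_corr()`) before trusting a cut.
- Barcode correction accepts a unique Hamming-1 neighbor regardless of
  abundance; frequency-aware correction is out of scope.
- The DEG procedure inherits the known selection property of
  logFC-prefiltered rank tests: the Bonferroni multiplier counts only
  tested genes. With balanced, truly-null alternatives this controls
  false positives as expected, but heavy compositional shifts between
  groups (e.g. a dominant cell-state change) can make non-target genes
  genuinely non-null after total-count normalization.
- `simulate_expression_for_qc()` requires enough baseline cells that
  the planted high-UMI cells fit strictly inside the top-2% slice; it
  validates this and refuses impossible configurations.
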