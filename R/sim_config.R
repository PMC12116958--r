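#' Simulation configuration for the synthetic differentiation experiment
#'
#' Builds and validates the configuration driving the synthetic-data
#' generators. The defaults emulate a six-timepoint (D0--D10) in vitro
#' differentiation experiment whose 18 cell clusters fall into three
#' stages, with per-stage glycosylation-tag abundance ordered
#' stage 2 > stage 3 > stage 1 and per-stage new-to-total RNA ratio (NTR)
#' ordered stage 3 > stage 1 > stage 2. Each sample draws cells from all
#' clusters, weighted toward the clusters of its own stage
#' (`cluster_mix`), mirroring the overlap of timepoints and clusters seen
#' in real droplet experiments.
#'
#' @param n_samples Number of samples/timepoints. Samples are named
#'   `D0, D2, ...` and split evenly into three consecutive stages.
#' @param clusters_per_sample Clusters per sample; total clusters =
#'   `n_samples * clusters_per_sample` (default 18), split evenly into the
#'   three stages.
#' @param n_cells_per_sample Cells simulated per sample.
#' @param n_genes Genes in the expression matrices.
#' @param stage_of_cluster Optional integer vector in `{1,2,3}`, one entry
#'   per cluster, overriding the default even split.
#' @param glyco_mean_per_stage Mean glycosylation-tag UMIs per cell for
#'   stages 1--3. Default `c(10, 60, 30)` gives the stage 2 > stage 3 >
#'   stage 1 ordering.
#' @param ntr_per_stage True per-stage probability that a transcript is
#'   newly synthesised, i.e. the expected NTR. Default `c(0.45, 0.15, 0.60)`
#'   gives the stage 3 > stage 1 > stage 2 ordering.
#' @param tag_error_rate Per-base substitution probability applied to the
#'   15-bp tag on R2.
#' @param barcode_error_rate Per-base substitution probability applied to
#'   the cell barcode on R1 (off by default).
#' @param barcode_len,umi_len Lengths of the cell barcode and UMI on R1.
#' @param tag_len Tag length; fixed at 15.
#' @param tag_offset 0-based position of the tag on R2.
#' @param n_tags Number of tag species in the generated whitelist.
#' @param polya_len Length of the poly-A tail appended after the tag on R2.
#' @param read_dup_rate Expected number of extra (PCR-duplicate) reads per
#'   tag molecule.
#' @param dispersion Negative-binomial dispersion (1/size) for all count
#'   draws; 0.5 matches typical UMI over-dispersion.
#' @param cluster_mix Probability mass a sample places on clusters of its
#'   own stage; the remainder is split evenly over the other stages. Set to
#'   1 for samples that contain only their own stage's clusters.
#' @param total_umis_per_cell Expected total transcript UMIs per cell.
#' @param marker_frac Fraction of genes acting as stage markers (per
#'   stage), giving stages distinct expression programs.
#' @param marker_fc Fold change applied to a stage's marker genes in cells
#'   of that stage.
#' @param cluster_marker_frac,cluster_marker_fc Analogous small per-cluster
#'   expression program distinguishing clusters within a stage.
#' @param n_mito_genes Number of genes named with the `MT-` prefix.
#' @param n_deg_genes Number of genes planted with a differential-expression
#'   effect between `deg_groups`.
#' @param deg_fold_change Multiplicative fold change for planted genes.
#' @param deg_groups `NULL`, or `list(a = <cluster ids>, b = <cluster ids>)`
#'   naming the two cluster groups the planted fold change separates.
#' @param seed Integer seed; all generator randomness flows from it.
#'
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_cells_per_sample = 50, n_genes = 100)
#' cfg$n_clusters
#' @export
sim_config <- function(n_samples = 6L,
                       clusters_per_sample = 3L,
                       n_cells_per_sample = 300L,
                       n_genes = 600L,
                       stage_of_cluster = NULL,
                       glyco_mean_per_stage = c(10, 60, 30),
                       ntr_per_stage = c(0.45, 0.15, 0.60),
                       tag_error_rate = 0,
                       barcode_error_rate = 0,
                       barcode_len = 16L,
                       umi_len = 12L,
                       tag_len = 15L,
                       tag_offset = 0L,
                       n_tags = 4L,
                       polya_len = 25L,
                       read_dup_rate = 0,
                       dispersion = 0.5,
                       cluster_mix = 0.6,
                       total_umis_per_cell = 2000,
                       marker_frac = 0.10,
                       marker_fc = 3,
                       cluster_marker_frac = 0.02,
                       cluster_marker_fc = 1.5,
                       n_mito_genes = 10L,
                       n_deg_genes = 0L,
                       deg_fold_change = 2,
                       deg_groups = NULL,
                       seed = 1L) {
  counts <- c(n_samples = n_samples, clusters_per_sample = clusters_per_sample,
              n_cells_per_sample = n_cells_per_sample, n_genes = n_genes,
              barcode_len = barcode_len, umi_len = umi_len,
              n_tags = n_tags)
  if (any(counts < 1)) {
    stop("all counts must be positive; offending: ",
         paste(names(counts)[counts < 1], collapse = ", "))
  }
  if (tag_len != 15L) stop("`tag_len` is fixed at 15")
  probs <- c(tag_error_rate = tag_error_rate,
             barcode_error_rate = barcode_error_rate,
             cluster_mix = cluster_mix)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(ntr_per_stage < 0 | ntr_per_stage > 1)) {
    stop("`ntr_per_stage` values must lie in [0, 1]")
  }
  if (length(ntr_per_stage) != 3L || length(glyco_mean_per_stage) != 3L) {
    stop("`ntr_per_stage` and `glyco_mean_per_stage` need one value per stage (3)")
  }
  if (any(glyco_mean_per_stage <= 0)) stop("`glyco_mean_per_stage` must be positive")
  if (dispersion <= 0) stop("`dispersion` must be positive")
  if (tag_offset < 0) stop("`tag_offset` must be >= 0")

  n_clusters <- as.integer(n_samples * clusters_per_sample)
  if (is.null(stage_of_cluster)) {
    stage_of_cluster <- as.integer(cut(seq_len(n_clusters), 3L, labels = FALSE))
  }
  if (length(stage_of_cluster) != n_clusters ||
      !all(stage_of_cluster %in% 1:3)) {
    stop("`stage_of_cluster` must map each of the ", n_clusters,
         " clusters to a stage in {1,2,3}")
  }
  if (!is.null(deg_groups)) {
    if (!is.list(deg_groups) || !all(c("a", "b") %in% names(deg_groups))) {
      stop("`deg_groups` must be a list with elements `a` and `b`")
    }
    if (length(intersect(deg_groups$a, deg_groups$b)) > 0L) {
      stop("`deg_groups$a` and `deg_groups$b` must be disjoint cluster sets")
    }
  }

  structure(list(
    n_samples = as.integer(n_samples),
    sample_names = paste0("D", seq(0L, by = 2L, length.out = n_samples)),
    sample_stage = as.integer(cut(seq_len(n_samples), 3L, labels = FALSE)),
    clusters_per_sample = as.integer(clusters_per_sample),
    n_clusters = n_clusters,
    n_cells_per_sample = as.integer(n_cells_per_sample),
    n_genes = as.integer(n_genes),
    stage_of_cluster = as.integer(stage_of_cluster),
    glyco_mean_per_stage = glyco_mean_per_stage,
    ntr_per_stage = ntr_per_stage,
    tag_error_rate = tag_error_rate,
    barcode_error_rate = barcode_error_rate,
    barcode_len = as.integer(barcode_len),
    umi_len = as.integer(umi_len),
    tag_len = 15L,
    tag_offset = as.integer(tag_offset),
    n_tags = as.integer(n_tags),
    polya_len = as.integer(polya_len),
    read_dup_rate = read_dup_rate,
    dispersion = dispersion,
    cluster_mix = cluster_mix,
    total_umis_per_cell = total_umis_per_cell,
    marker_frac = marker_frac,
    marker_fc = marker_fc,
    cluster_marker_frac = cluster_marker_frac,
    cluster_marker_fc = cluster_marker_fc,
    n_mito_genes = as.integer(n_mito_genes),
    n_deg_genes = as.integer(n_deg_genes),
    deg_fold_change = deg_fold_change,
    deg_groups = deg_groups,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  samples:", paste(x$sample_names, collapse = " "),
      sprintf("(%d cells each)\n", x$n_cells_per_sample))
  cat("  clusters:", x$n_clusters, "in 3 stages;",
      "genes:", x$n_genes, "\n")
  cat("  glyco mean/stage:", paste(x$glyco_mean_per_stage, collapse = " "),
      " NTR/stage:", paste(x$ntr_per_stage, collapse = " "), "\n")
  cat("  tag error:", x$tag_error_rate, " seed:", x$seed, "\n")
  invisible(x)
}
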