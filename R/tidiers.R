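# broom-style tidiers for the package's result objects.

#' Tidy a demultiplexing result into its tally table
#'
#' @param x A `glyco_demux` object.
#' @param ... Unused.
#' @return One row per tally category with columns `category`, `reads`.
#' @method tidy glyco_demux
#' @export
tidy.glyco_demux <- function(x, ...) {
  r <- x$report
  tibble::tibble(
    category = c("valid", "invalid", "ambiguous", "unassigned", "skipped"),
    reads = c(r$valid, r$invalid, r$ambiguous, r$unassigned, r$skipped)
  )
}

#' @rdname tidy.glyco_demux
#' @return `glance()`: a one-row summary (reads seen, valid fraction,
#'   UMIs counted, matrix dimensions).
#' @method glance glyco_demux
#' @export
glance.glyco_demux <- function(x, ...) {
  r <- x$report
  tibble::tibble(
    reads_seen = r$reads_seen,
    valid_fraction = r$valid / max(1L, r$reads_seen),
    umis_counted = r$umi_counted,
    n_cells = nrow(x$matrix),
    n_tags = ncol(x$matrix)
  )
}

#' Tidy a stage partition
#'
#' @param x A `stage_partition` from [partition_stages()].
#' @param ... Unused.
#' @return A plain tibble with `cluster` and `stage`.
#' @method tidy stage_partition
#' @export
tidy.stage_partition <- function(x, ...) {
  tibble::tibble(cluster = x$cluster, stage = x$stage)
}

#' One-row summary of a differential-expression table
#'
#' @param x A `deg_table` from [find_degs()].
#' @param ... Unused.
#' @return Tibble with the number of genes tested, number significant,
#'   and the significance level used.
#' @method glance deg_table
#' @export
glance.deg_table <- function(x, ...) {
  tibble::tibble(
    n_tested = attr(x, "n_tested"),
    n_significant = sum(x$significant),
    alpha = attr(x, "alpha")
  )
}

#' One-row summary of a QC filtering result
#'
#' @param x A `qc_result` from [qc_filter()].
#' @param ... Unused.
#' @return Tibble of input/output dimensions and per-rule removals.
#' @method glance qc_result
#' @export
glance.qc_result <- function(x, ...) {
  r <- x$report
  tibble::tibble(
    n_cells_in = r$n_cells_in, n_cells_out = r$n_cells_out,
    n_genes_in = r$n_genes_in, n_genes_out = r$n_genes_out,
    removed_gene_rule = length(r$removed_min_or_top_genes),
    removed_top_umi = length(r$removed_top_umi),
    removed_mito = length(r$removed_mito),
    removed_genes = length(r$removed_genes)
  )
}
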