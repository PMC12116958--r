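#' Validate a new/old/total count matrix triple
#'
#' Checks that the three matrices share shape and dimnames, that all
#' entries are non-negative, and that `new + old = total` holds exactly.
#' When `old` is omitted it is derived as `total - new` and checked for
#' non-negativity.
#'
#' @param new,total Cell x gene count matrices (sparse or dense) with
#'   identical dimnames.
#' @param old Optional matching matrix; derived when `NULL`.
#' @return A list of class `tri_counts` with elements `new`, `old`,
#'   `total` as sparse matrices.
#' @export
validate_tri <- function(new, total, old = NULL) {
  as_sp <- function(m) methods::as(methods::as(m, "sparseMatrix"), "CsparseMatrix")
  new <- as_sp(new); total <- as_sp(total)
  if (!identical(dim(new), dim(total))) {
    stop("`new` and `total` must share dimensions")
  }
  if (!identical(dimnames(new), dimnames(total))) {
    stop("`new` and `total` must share row/column names")
  }
  check_nonneg <- function(m, label) {
    if (any(m@x < 0)) {
      idx <- which(as.matrix(m) < 0, arr.ind = TRUE)[1L, ]
      stop("`", label, "` has a negative entry at cell '",
           rownames(m)[idx[1L]] %||% idx[1L], "', gene '",
           colnames(m)[idx[2L]] %||% idx[2L], "'")
    }
  }
  check_nonneg(new, "new"); check_nonneg(total, "total")
  excess <- new - total
  if (any(excess@x > 0)) {
    idx <- which(as.matrix(excess) > 0, arr.ind = TRUE)[1L, ]
    stop("new > total at cell '", rownames(new)[idx[1L]] %||% idx[1L],
         "', gene '", colnames(new)[idx[2L]] %||% idx[2L],
         "': conservation new + old = total is violated")
  }
  if (is.null(old)) {
    old <- total - new
  } else {
    old <- as_sp(old)
    if (!identical(dim(old), dim(total)) ||
        !identical(dimnames(old), dimnames(total))) {
      stop("`old` must share dimensions and names with `total`")
    }
    check_nonneg(old, "old")
    resid <- new + old - total
    if (length(resid@x) && any(resid@x != 0)) {
      idx <- which(as.matrix(resid) != 0, arr.ind = TRUE)[1L, ]
      stop("new + old != total at cell '",
           rownames(new)[idx[1L]] %||% idx[1L], "', gene '",
           colnames(new)[idx[2L]] %||% idx[2L], "'")
    }
  }
  structure(list(new = new, old = old, total = total), class = "tri_counts")
}

#' Per-cell new-to-total RNA ratio
#'
#' `NTR_c = sum_g new_cg / sum_g total_cg` — the ratio of summed counts,
#' which is robust to genes with zero totals. Cells with zero total
#' counts get `NA` (flagged missing, never 0).
#'
#' @param tri A `tri_counts` triple from [validate_tri()].
#' @return A tibble of class `ntr_cells`: `barcode`, `new_umis`,
#'   `total_umis`, `ntr`.
#' @export
cell_ntr <- function(tri) {
  stopifnot(inherits(tri, "tri_counts"))
  new_sum <- Matrix::rowSums(tri$new)
  tot_sum <- Matrix::rowSums(tri$total)
  ntr <- ifelse(tot_sum > 0, new_sum / tot_sum, NA_real_)
  out <- tibble::tibble(
    barcode = rownames(tri$total) %||% as.character(seq_along(tot_sum)),
    new_umis = as.numeric(new_sum),
    total_umis = as.numeric(tot_sum),
    ntr = as.numeric(ntr)
  )
  class(out) <- c("ntr_cells", class(out))
  out
}

#' Aggregate per-cell NTR by cluster
#'
#' @param ntr An `ntr_cells` tibble from [cell_ntr()].
#' @param clusters Tibble with columns `barcode` and `cluster` (extra
#'   grouping columns such as `stage` may be named via `by`), or a vector
#'   of cluster labels aligned with `ntr`.
#' @param aggregator `"mean"` (default) or `"median"` over per-cell
#'   ratios, or `"pooled"` for `sum(new)/sum(total)` within the cluster.
#' @param by Grouping column when `clusters` is a tibble.
#' @return Tibble with `cluster`, `n_cells` (cells with non-zero totals)
#'   and `ntr`; clusters with no valid cell get `NA`.
#' @export
cluster_ntr <- function(ntr, clusters, aggregator = c("mean", "median", "pooled"),
                        by = "cluster") {
  aggregator <- match.arg(aggregator)
  stopifnot(inherits(ntr, "ntr_cells") || is.data.frame(ntr))
  if (is.data.frame(clusters)) {
    idx <- match(ntr$barcode, clusters$barcode)
    if (anyNA(idx[!is.na(ntr$ntr)])) {
      stop("every cell with counts needs a cluster label")
    }
    grp <- clusters[[by]][idx]
  } else {
    if (length(clusters) != nrow(ntr)) {
      stop("`clusters` vector must have one label per cell")
    }
    grp <- clusters
  }
  df <- dplyr::mutate(tibble::as_tibble(ntr), .cluster = grp)
  dplyr::summarise(
    dplyr::group_by(df, cluster = .data$.cluster),
    n_cells = sum(!is.na(.data$ntr)),
    ntr = switch(aggregator,
      mean = if (any(!is.na(.data$ntr))) mean(.data$ntr, na.rm = TRUE) else NA_real_,
      median = if (any(!is.na(.data$ntr))) stats::median(.data$ntr, na.rm = TRUE) else NA_real_,
      pooled = if (sum(.data$total_umis) > 0) {
        sum(.data$new_umis) / sum(.data$total_umis)
      } else NA_real_
    ),
    .groups = "drop"
  )
}
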