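#' Quality-control thresholds
#'
#' The four filtering rules, applied in order: (1) cells with fewer than
#' `min_genes` detected genes, or a detected-gene count in the top
#' `top_gene_pct` percent, are excluded; (2) cells with a total UMI count
#' in the top `top_umi_pct` percent are excluded; (3) cells with
#' mitochondrial content above `max_mito_pct` percent are excluded;
#' (4) genes expressed in fewer than `min_cells_per_gene` retained cells
#' are excluded.
#'
#' @param min_genes Minimum detected genes per cell (default 200).
#' @param top_gene_pct,top_umi_pct Top-percentile cuts (default 2).
#' @param max_mito_pct Maximum mitochondrial percentage (default 20).
#' @param min_cells_per_gene Minimum cells per gene (default 5).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 200L, top_gene_pct = 2,
                          top_umi_pct = 2, max_mito_pct = 20,
                          min_cells_per_gene = 5L) {
  pct <- c(top_gene_pct = top_gene_pct, top_umi_pct = top_umi_pct,
           max_mito_pct = max_mito_pct)
  if (any(pct <= 0 | pct >= 100)) stop("percentages must lie in (0, 100)")
  if (min_genes < 1L || min_cells_per_gene < 1L) stop("counts must be positive")
  structure(list(min_genes = as.integer(min_genes),
                 top_gene_pct = top_gene_pct, top_umi_pct = top_umi_pct,
                 max_mito_pct = max_mito_pct,
                 min_cells_per_gene = as.integer(min_cells_per_gene)),
            class = "qc_thresholds")
}

#' Filter a cell-by-gene count matrix with the standard QC rules
#'
#' Applies the four rules of [qc_thresholds()] sequentially: each
#' percentile cut uses the nearest-rank order statistic at rank
#' `ceiling((1 - pct/100) * n)` over the cells entering that rule, and
#' removes cells strictly above the cut. The gene rule runs last, on the
#' retained cells. Because the top-percentile rules are relative, a
#' second run on the output can remove further cells; the absolute rules
#' are idempotent.
#'
#' @param counts Sparse cells x genes count matrix with dimnames.
#' @param thresholds A [qc_thresholds()].
#' @param mito_genes Character vector of mitochondrial gene names;
#'   defaults to genes whose name starts with `"MT-"`.
#' @return A list of class `qc_result`: `matrix` (the filtered matrix)
#'   and `report` with per-rule removals and retained dimensions.
#' @export
qc_filter <- function(counts, thresholds = qc_thresholds(),
                      mito_genes = NULL) {
  if (nrow(counts) == 0L || ncol(counts) == 0L) stop("`counts` is empty")
  if (is.null(mito_genes)) {
    mito_genes <- grep("^MT-", colnames(counts), value = TRUE)
  }
  genes_per_cell <- Matrix::rowSums(counts > 0)
  umis_per_cell <- Matrix::rowSums(counts)
  mito_umis <- if (length(mito_genes)) {
    Matrix::rowSums(counts[, colnames(counts) %in% mito_genes, drop = FALSE])
  } else {
    numeric(nrow(counts))
  }
  mito_pct <- ifelse(umis_per_cell > 0, 100 * mito_umis / umis_per_cell, 0)

  cells <- rownames(counts)
  alive <- rep(TRUE, length(cells))

  top_cut <- function(v, pct) nearest_rank(v, (100 - pct) / 100)

  # rule 1: low gene count OR top-percent gene count
  cut1 <- top_cut(genes_per_cell[alive], thresholds$top_gene_pct)
  r1 <- alive & (genes_per_cell < thresholds$min_genes | genes_per_cell > cut1)
  alive <- alive & !r1
  # rule 2: top-percent UMI count, among survivors
  cut2 <- top_cut(umis_per_cell[alive], thresholds$top_umi_pct)
  r2 <- alive & umis_per_cell > cut2
  alive <- alive & !r2
  # rule 3: mitochondrial content
  r3 <- alive & mito_pct > thresholds$max_mito_pct
  alive <- alive & !r3

  kept <- counts[alive, , drop = FALSE]
  if (nrow(kept) == 0L) stop("no cells survive the QC filters")
  # rule 4: genes expressed in too few retained cells
  cells_per_gene <- Matrix::colSums(kept > 0)
  gene_keep <- cells_per_gene >= thresholds$min_cells_per_gene
  kept <- kept[, gene_keep, drop = FALSE]
  if (ncol(kept) == 0L) stop("no genes survive the QC filters")

  structure(list(
    matrix = kept,
    report = list(
      n_cells_in = length(cells), n_genes_in = length(gene_keep),
      removed_min_or_top_genes = cells[r1],
      removed_top_umi = cells[r2],
      removed_mito = cells[r3],
      removed_genes = colnames(counts)[!gene_keep],
      n_cells_out = nrow(kept), n_genes_out = ncol(kept),
      thresholds = thresholds
    )
  ), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  r <- x$report
  cat("<qc_result>", r$n_cells_in, "->", r$n_cells_out, "cells;",
      r$n_genes_in, "->", r$n_genes_out, "genes\n")
  cat("  removed: gene-count rule", length(r$removed_min_or_top_genes),
      "| top-UMI", length(r$removed_top_umi),
      "| mito", length(r$removed_mito),
      "| genes", length(r$removed_genes), "\n")
  invisible(x)
}

#' Library-size log-normalization
#'
#' `x_cg -> ln(1 + scale * x_cg / total_c)` with `total_c` the cell's
#' summed counts — total-count normalization followed by the log
#' transform, scale-invariant per cell.
#'
#' @param counts Sparse cells x genes count matrix (post-QC; every cell
#'   must have positive total counts).
#' @param scale Scale factor (default 10,000).
#' @return Sparse matrix of normalized values.
#' @export
lognormalize <- function(counts, scale = 1e4) {
  totals <- Matrix::rowSums(counts)
  if (any(totals == 0)) {
    stop("cell '", rownames(counts)[first_true(totals == 0)],
         "' has zero total counts; run qc_filter() first")
  }
  out <- methods::as(methods::as(counts, "sparseMatrix"), "CsparseMatrix")
  out@x <- log1p(scale * out@x / totals[out@i + 1L])
  out
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided test of identical distributions. For pooled sample sizes of
#' at most `exact_max` the null distribution of the rank sum is obtained
#' by exact enumeration of all group assignments (ties handled through
#' midranks), with `p = min(1, 2 min(P(W <= w), P(W >= w)))`. Larger
#' samples use the normal approximation with tie correction and a 0.5
#' continuity correction.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param exact_max Largest pooled size for exact enumeration (default 12).
#' @return List with `statistic` (the Mann-Whitney U of group `a`) and
#'   `p.value`.
#' @export
wilcoxon_rank_sum <- function(a, b, exact_max = 12L) {
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  w <- sum(r[seq_len(na)])
  u <- w - na * (na + 1) / 2

  if (n <= exact_max) {
    combs <- utils::combn(n, na)
    sums <- colSums(matrix(r[combs], nrow = na))
    p_low <- mean(sums <= w + 1e-9)
    p_high <- mean(sums >= w - 1e-9)
    p <- min(1, 2 * min(p_low, p_high))
    return(list(statistic = u, p.value = p))
  }

  ties <- table(r)
  mu <- na * nb / 2
  sigma2 <- (na * nb / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(statistic = u, p.value = 1))
  z <- u - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  list(statistic = u, p.value = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Wilcoxon differential expression with fraction/logFC/Bonferroni filters
#'
#' For each gene, the fraction of expressing (non-zero) cells is computed
#' in both groups and the average log fold change as
#' `ln(mean(expm1(x_A)) + eps) - ln(mean(expm1(x_B)) + eps)` on the
#' log-normalized values. Only genes expressed in more than `min_pct` of
#' the cells of either group *and* with `|logFC|` above `logfc_threshold`
#' are tested ([wilcoxon_rank_sum()]); raw p-values are
#' Bonferroni-corrected over the genes actually tested (or over all genes
#' when `bonferroni_all`). A gene is significant when `p_adj < alpha`,
#' `|logFC| > logfc_threshold`, and `max(pct_1, pct_2) > min_pct`.
#'
#' @param norm Sparse cells x genes matrix of log-normalized expression.
#' @param cells_a,cells_b Disjoint, non-empty barcode vectors (or row
#'   indices) defining the two groups.
#' @param min_pct Expression-fraction threshold (default 0.10).
#' @param logfc_threshold Absolute natural-log fold-change threshold
#'   (default 0.25).
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @param eps Stabilizer inside the logs (default 1e-9).
#' @param bonferroni_all Multiply by all genes instead of tested genes.
#' @return A tibble of class `deg_table`, one row per gene passing the
#'   pre-filter: `gene`, `avg_logFC`, `pct_1`, `pct_2`, `p_raw`, `p_adj`,
#'   `significant`; attribute `n_tested` records the Bonferroni
#'   multiplier's basis.
#' @export
find_degs <- function(norm, cells_a, cells_b, min_pct = 0.10,
                      logfc_threshold = 0.25, alpha = 0.05, eps = 1e-9,
                      bonferroni_all = FALSE) {
  resolve <- function(x) {
    if (is.character(x)) {
      idx <- match(x, rownames(norm))
      if (anyNA(idx)) stop("unknown barcode: ", x[first_true(is.na(idx))])
      idx
    } else as.integer(x)
  }
  ia <- resolve(cells_a); ib <- resolve(cells_b)
  if (length(ia) == 0L || length(ib) == 0L) stop("both groups must be non-empty")
  if (length(intersect(ia, ib)) > 0L) stop("groups must be disjoint")

  ma <- norm[ia, , drop = FALSE]
  mb <- norm[ib, , drop = FALSE]
  pct1 <- Matrix::colMeans(ma > 0)
  pct2 <- Matrix::colMeans(mb > 0)
  de_log <- function(m) {
    m@x <- expm1(m@x)
    Matrix::colMeans(m)
  }
  logfc <- log(de_log(ma) + eps) - log(de_log(mb) + eps)

  pre <- pmax(pct1, pct2) > min_pct & abs(logfc) > logfc_threshold
  tested <- which(pre)
  n_tested <- if (bonferroni_all) ncol(norm) else length(tested)

  p_raw <- rep(NA_real_, length(tested))
  if (length(tested) > 0L) {
    da <- as.matrix(ma[, tested, drop = FALSE])
    db <- as.matrix(mb[, tested, drop = FALSE])
    p_raw <- vapply(seq_along(tested), function(j) {
      wilcoxon_rank_sum(da[, j], db[, j])$p.value
    }, numeric(1))
  }
  p_adj <- pmin(1, p_raw * n_tested)

  out <- tibble::tibble(
    gene = colnames(norm)[tested],
    avg_logFC = unname(logfc[tested]),
    pct_1 = unname(pct1[tested]),
    pct_2 = unname(pct2[tested]),
    p_raw = p_raw,
    p_adj = p_adj
  )
  out$significant <- out$p_adj < alpha &
    abs(out$avg_logFC) > logfc_threshold &
    pmax(out$pct_1, out$pct_2) > min_pct
  out <- dplyr::arrange(out, .data$p_adj, dplyr::desc(abs(.data$avg_logFC)))
  attr(out, "n_tested") <- n_tested
  attr(out, "alpha") <- alpha
  class(out) <- c("deg_table", class(out))
  out
}
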