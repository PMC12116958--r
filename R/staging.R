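#' Per-cluster pseudo-bulk expression profiles
#'
#' Row `c` of the profile is the per-gene mean of (log-normalized)
#' expression over the cells of cluster `c`. Clusters with no cells are
#' dropped with a warning.
#'
#' @param norm Sparse cells x genes matrix (log-normalized by default
#'   upstream; raw counts work if that is what correlations should use).
#' @param clusters Tibble with `barcode` and `cluster` columns, or a
#'   vector of cluster labels aligned with the matrix rows.
#' @return A list of class `pseudobulk`: `profile` (clusters x genes
#'   dense matrix, rows named by cluster) and `sizes` (named cell
#'   counts).
#' @export
pseudobulk <- function(norm, clusters) {
  if (is.data.frame(clusters)) {
    idx <- match(rownames(norm), clusters$barcode)
    if (anyNA(idx)) {
      stop("every cell needs a cluster label; missing for e.g. ",
           rownames(norm)[first_true(is.na(idx))])
    }
    grp <- clusters$cluster[idx]
  } else {
    if (length(clusters) != nrow(norm)) {
      stop("`clusters` must have one label per cell")
    }
    grp <- clusters
  }
  lv <- sort(unique(grp))
  sizes <- table(factor(grp, levels = lv))
  sums <- rowsum(as.matrix(norm), group = factor(grp, levels = lv))
  profile <- sums / as.vector(sizes)
  structure(list(profile = profile,
                 sizes = stats::setNames(as.integer(sizes), lv)),
            class = "pseudobulk")
}

#' Spearman correlation matrix between cluster profiles
#'
#' @param pb A `pseudobulk` object (or a clusters x genes matrix).
#' @return Symmetric matrix of Spearman correlations with unit diagonal;
#'   average ranks for ties. Constant profiles yield `NA` rows/columns
#'   (flagged with a warning), their diagonal still 1.
#' @export
spearman_matrix <- function(pb) {
  profile <- if (inherits(pb, "pseudobulk")) pb$profile else as.matrix(pb)
  if (nrow(profile) < 2L || ncol(profile) < 2L) {
    stop("need at least 2 clusters and 2 genes")
  }
  const <- apply(profile, 1L, function(x) length(unique(x)) == 1L)
  if (any(const)) {
    warning("constant profile for cluster(s) ",
            paste(rownames(profile)[const], collapse = ", "),
            "; correlations set to NA")
  }
  rho <- suppressWarnings(stats::cor(t(profile), method = "spearman"))
  diag(rho) <- 1
  rho
}

#' Partition clusters into differentiation stages
#'
#' Agglomerative hierarchical clustering (average linkage by default) on
#' the distance `1 - rho`, cut into `k` groups. Stage ids are relabeled
#' by first appearance in cluster-index order, making the output
#' deterministic; agreement with any reference labeling should be judged
#' up to stage-id permutation (e.g. by adjusted Rand index).
#'
#' @param corr Symmetric correlation matrix from [spearman_matrix()].
#' @param k Number of stages (default 3).
#' @param linkage `hclust` agglomeration method (default `"average"`).
#' @return A tibble of class `stage_partition` with columns `cluster`
#'   and `stage`; the `hclust` tree is kept in the `"tree"` attribute.
#' @export
partition_stages <- function(corr, k = 3L, linkage = "average") {
  if (k > nrow(corr)) {
    stop("k = ", k, " exceeds the number of clusters (", nrow(corr), ")")
  }
  if (anyNA(corr)) stop("correlation matrix contains NA; drop constant clusters first")
  d <- stats::as.dist(1 - corr)
  tree <- stats::hclust(d, method = linkage)
  raw <- stats::cutree(tree, k = k)
  # relabel stages by first appearance so ids do not depend on merge order
  stage <- match(raw, unique(raw))
  out <- tibble::tibble(
    cluster = rownames(corr) %||% as.character(seq_len(nrow(corr))),
    stage = as.integer(stage)
  )
  attr(out, "tree") <- tree
  class(out) <- c("stage_partition", class(out))
  out
}
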