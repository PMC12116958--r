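#' Centered log-ratio transform of a count vector
#'
#' `out_i = ln(x_i + c) - mean_j ln(x_j + c)` with pseudocount `c`. The
#' components of the result sum to zero; a length-one composition maps
#' to 0.
#'
#' @param x Non-negative numeric vector (counts over tag species).
#' @param pseudocount Positive pseudocount added before the log
#'   (default 1).
#' @return Numeric vector of the same length.
#' @examples
#' clr_transform(c(7, 1))  # +/- log(2)
#' @export
clr_transform <- function(x, pseudocount = 1) {
  if (length(x) < 1L) stop("`x` must have length >= 1")
  if (pseudocount <= 0) stop("`pseudocount` must be positive")
  if (any(x < 0)) stop("`x` must be non-negative")
  lx <- log(x + pseudocount)
  lx - mean(lx)
}

#' Per-sample CLR normalization of glycosylation-tag UMIs
#'
#' Normalizes the tag UMI matrix within each sample independently and
#' returns one score per cell used for high/low stratification.
#'
#' With a single tag species the per-cell CLR across tags is degenerate
#' (always 0), so the default `"total"` mode applies the CLR across the
#' cells of a sample to the per-cell total tag count: each cell's score is
#' `ln(total + c)` centered by the within-sample mean of `ln(total + c)`.
#' This across-cells CLR is the standard normalization for single-species
#' tag counts and is the score all downstream stratification uses.
#' `"per_tag"` mode additionally returns the per-cell CLR over tag
#' species (each cell's values summing to zero).
#'
#' @param mat Cells x tags UMI count matrix (rows named by barcode).
#' @param labels Tibble with columns `barcode` and `sample` covering every
#'   row of `mat` (extra columns such as `cluster`/`stage` are carried
#'   through).
#' @param pseudocount Positive pseudocount (default 1).
#' @param mode `"total"` (default) or `"per_tag"`.
#' @return `"total"`: a `glyco_scores` tibble with columns `barcode`,
#'   `sample`, `raw_total`, `score` (plus carried label columns).
#'   `"per_tag"`: a long tibble `barcode`, `sample`, `tag`, `clr`.
#' @export
normalize_per_sample <- function(mat, labels, pseudocount = 1,
                                 mode = c("total", "per_tag")) {
  mode <- match.arg(mode)
  if (pseudocount <= 0) stop("`pseudocount` must be positive")
  stopifnot(is.data.frame(labels), all(c("barcode", "sample") %in% names(labels)))
  bc <- rownames(mat)
  idx <- match(bc, labels$barcode)
  if (anyNA(idx) || anyNA(labels$sample[idx])) {
    stop("every cell in the matrix needs a sample label; missing for e.g. ",
         bc[first_true(is.na(idx) | is.na(labels$sample[idx]))])
  }
  samp <- labels$sample[idx]

  if (mode == "per_tag") {
    lx <- log(as.matrix(mat) + pseudocount)
    clr <- lx - rowMeans(lx)
    out <- tibble::tibble(
      barcode = rep(bc, times = ncol(mat)),
      sample = rep(samp, times = ncol(mat)),
      tag = rep(colnames(mat), each = nrow(mat)),
      clr = as.vector(clr)
    )
    return(out)
  }

  totals <- Matrix::rowSums(mat)
  lt <- log(totals + pseudocount)
  centered <- lt - stats::ave(lt, samp, FUN = mean)
  out <- tibble::tibble(barcode = bc, sample = samp,
                        raw_total = as.numeric(totals),
                        score = as.numeric(centered))
  extra <- setdiff(names(labels), c("barcode", "sample"))
  for (col in extra) out[[col]] <- labels[[col]][idx]
  class(out) <- c("glyco_scores", class(out))
  out
}

#' Split cells into glycosylation-high and -low classes at the median
#'
#' Cells with a score strictly above the median are `high`; cells at or
#' below the median (including all cells when scores are constant) are
#' `low`. The labels are invariant under any strictly increasing
#' transform of the scores.
#'
#' @param scores Numeric vector of per-cell normalized scores (>= 2 cells).
#' @return Character vector `"high"`/`"low"`.
#' @export
median_split <- function(scores) {
  if (length(scores) < 2L) stop("median_split() needs at least 2 cells")
  m <- stats::median(scores)
  ifelse(scores > m, "high", "low")
}

#' Stratify cells into top/bottom quantile classes
#'
#' With threshold quantile `q` (default 0.20, the top/bottom-20% design),
#' cells at or below the `q`-quantile are `low20`, cells at or above the
#' `(1-q)`-quantile are `high20`, the rest `mid`. Quantiles use the
#' nearest-rank order statistic: the low cut is the value at rank
#' `ceiling(q * n)` and the high cut the value at rank
#' `n - ceiling(q * n) + 1`, so distinct values give exactly
#' `ceiling(q * n)` cells per extreme stratum. Cells qualifying for both
#' extremes (heavy ties, e.g. constant input) are assigned `mid` with a
#' warning.
#'
#' @param values Numeric vector of per-cell values (normalized scores by
#'   default upstream; any per-cell abundance works).
#' @param q Quantile in (0, 0.5).
#' @return Character vector `"high20"`/`"mid"`/`"low20"`.
#' @export
quantile_strata <- function(values, q = 0.20) {
  if (q <= 0 || q >= 0.5) stop("`q` must lie in (0, 0.5)")
  n <- length(values)
  if (n < ceiling(1 / q)) {
    stop("need at least ", ceiling(1 / q), " cells for q = ", q)
  }
  k <- ceiling(q * n)
  s <- sort(values)
  low_cut <- s[k]
  high_cut <- s[n - k + 1L]
  low <- values <= low_cut
  high <- values >= high_cut
  both <- low & high
  if (any(both)) {
    warning("ties span both strata for ", sum(both),
            " cells; assigning them to 'mid'")
    low[both] <- FALSE
    high[both] <- FALSE
  }
  out <- rep("mid", n)
  out[low] <- "low20"
  out[high] <- "high20"
  out
}

#' Score glycosylation and attach class labels
#'
#' Convenience wrapper: per-sample CLR normalization, then the median
#' high/low split and the top/bottom-`q` strata, both computed within
#' each sample on the normalized score.
#'
#' @inheritParams normalize_per_sample
#' @param q Quantile for [quantile_strata()].
#' @param stratify_on `"score"` (default, the normalized value) or
#'   `"raw"` (raw total tag UMIs).
#' @return A `glyco_scores` tibble with added columns `class_median` and
#'   `class_quantile`.
#' @export
score_glyco <- function(mat, labels, pseudocount = 1, q = 0.20,
                        stratify_on = c("score", "raw")) {
  stratify_on <- match.arg(stratify_on)
  scores <- normalize_per_sample(mat, labels, pseudocount = pseudocount)
  v <- if (stratify_on == "score") scores$score else scores$raw_total
  scores$class_median <- unsplit(
    lapply(split(v, scores$sample), median_split), scores$sample
  )
  scores$class_quantile <- unsplit(
    lapply(split(v, scores$sample), quantile_strata, q = q), scores$sample
  )
  scores
}

#' Aggregate glycosylation scores per cluster (or any grouping)
#'
#' @param scores A `glyco_scores` tibble containing the grouping column.
#' @param by Grouping column name (default `"cluster"`).
#' @param aggregator `"mean"` (default) or `"median"`.
#' @return Tibble with the group, cell count, and aggregated score.
#' @export
glyco_cluster_summary <- function(scores, by = "cluster",
                                  aggregator = c("mean", "median")) {
  aggregator <- match.arg(aggregator)
  if (!by %in% names(scores)) stop("column '", by, "' not found in scores")
  fun <- if (aggregator == "mean") mean else stats::median
  dplyr::summarise(
    dplyr::group_by(scores, dplyr::across(dplyr::all_of(by))),
    n_cells = dplyr::n(),
    glyco = fun(.data$score),
    .groups = "drop"
  )
}
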