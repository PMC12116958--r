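# ggplot2 views of the result objects. All return a ggplot the caller
# can restyle.

#' Violin plot of glycosylation scores by class or grouping
#'
#' @param scores A `glyco_scores` tibble (see [score_glyco()]).
#' @param by Column to group on (default `"class_median"`).
#' @return A ggplot.
#' @export
plot_glyco <- function(scores, by = "class_median") {
  if (!by %in% names(scores)) stop("column '", by, "' not in scores")
  ggplot2::ggplot(scores, ggplot2::aes(
    x = factor(.data[[by]]), y = .data$score, fill = factor(.data[[by]])
  )) +
    ggplot2::geom_violin(show.legend = FALSE) +
    ggplot2::labs(x = by, y = "normalized glycosylation score") +
    ggplot2::theme_minimal()
}

#' Per-cluster NTR bar chart
#'
#' @param ntr_clusters Output of [cluster_ntr()].
#' @return A ggplot.
#' @export
plot_ntr <- function(ntr_clusters) {
  ggplot2::ggplot(ntr_clusters, ggplot2::aes(
    x = factor(.data$cluster), y = .data$ntr
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "cluster", y = "new-to-total RNA ratio") +
    ggplot2::theme_minimal()
}

#' Heatmap of the between-cluster Spearman correlation matrix
#'
#' @param corr Matrix from [spearman_matrix()].
#' @return A ggplot.
#' @export
plot_stage_corr <- function(corr) {
  df <- tibble::as_tibble(as.table(corr), .name_repair = "minimal")
  names(df) <- c("cluster_a", "cluster_b", "rho")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$cluster_a, y = .data$cluster_b, fill = .data$rho
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman ρ") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential-expression table
#'
#' @param object A `deg_table` from [find_degs()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot deg_table
#' @export
autoplot.deg_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$neglog10p <- -log10(pmax(df$p_adj, 1e-300))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$avg_logFC, y = .data$neglog10p, colour = .data$significant
  )) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "average logFC (natural log)",
                  y = expression(-log[10] ~ "adjusted p")) +
    ggplot2::theme_minimal()
}

#' Stage-level summary plot of an end-to-end pipeline run
#'
#' Shows mean glycosylation score and mean NTR per inferred stage side by
#' side — the two orderings the integrated summary reports.
#'
#' @param object A `glyco_pipeline` from [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot glyco_pipeline
#' @export
autoplot.glyco_pipeline <- function(object, ...) {
  df <- tidyr::pivot_longer(object$stage_summary,
                            c("glyco", "ntr"),
                            names_to = "modality", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$stage), y = .data$value
  )) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~modality, scales = "free_y") +
    ggplot2::labs(x = "stage", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
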