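#' Simulate the cell table shared by all generators
#'
#' Draws the per-cell sample, cluster and stage assignments. Every sample
#' contains cells from all clusters, with probability mass `cluster_mix` on
#' the clusters of the sample's own stage and the remainder split evenly
#' across the other stages, so that within-sample contrasts between stages
#' exist (as in real timepoint experiments where clusters span samples).
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `barcode`, `sample`, `cluster`, `stage`,
#'   one row per cell. Deterministic given `config$seed`.
#' @export
simulate_cells <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n_total <- config$n_samples * config$n_cells_per_sample
    barcodes <- random_dna_unique(n_total, config$barcode_len)
    sample_id <- rep(seq_len(config$n_samples), each = config$n_cells_per_sample)
    stage_of_cluster <- config$stage_of_cluster
    cluster <- integer(n_total)
    for (s in seq_len(config$n_samples)) {
      own_stage <- config$sample_stage[s]
      own <- stage_of_cluster == own_stage
      w <- numeric(config$n_clusters)
      other_stages <- setdiff(unique(stage_of_cluster), own_stage)
      if (config$cluster_mix >= 1 || length(other_stages) == 0L) {
        w[own] <- 1 / sum(own)
      } else {
        w[own] <- config$cluster_mix / sum(own)
        for (os in other_stages) {
          in_os <- stage_of_cluster == os
          w[in_os] <- (1 - config$cluster_mix) / length(other_stages) / sum(in_os)
        }
      }
      idx <- which(sample_id == s)
      cluster[idx] <- sample(seq_len(config$n_clusters), length(idx),
                             replace = TRUE, prob = w)
    }
    tibble::tibble(
      barcode = barcodes,
      sample = config$sample_names[sample_id],
      cluster = cluster,
      stage = stage_of_cluster[cluster]
    )
  })
}

#' Generate a tag whitelist with guaranteed pairwise separation
#'
#' Draws random 15-nt tag sequences, rejecting candidates within Hamming
#' distance `min_dist` of an accepted tag, so that single-error reads match
#' a unique tag.
#'
#' @param n_tags Number of tags.
#' @param seed Integer seed.
#' @param min_dist Minimum pairwise Hamming distance (default 4).
#' @param tag_len Tag length (fixed 15 in the assay this emulates).
#' @return Character vector of tag sequences named `tag1`, `tag2`, ...
#' @export
generate_tag_whitelist <- function(n_tags = 4L, seed = 1L, min_dist = 4L,
                                   tag_len = 15L) {
  with_seed(seed, {
    tags <- character(0)
    while (length(tags) < n_tags) {
      cand <- random_dna(1L, tag_len)
      if (all(vapply(tags, function(t) hamming(cand, t), integer(1)) >= min_dist)) {
        tags <- c(tags, cand)
      }
    }
    stats::setNames(tags, paste0("tag", seq_len(n_tags)))
  })
}

check_tag_whitelist <- function(tags, min_dist = 4L) {
  if (length(tags) > 1L) {
    for (i in seq_len(length(tags) - 1L)) {
      for (j in seq(i + 1L, length(tags))) {
        d <- hamming(tags[[i]], tags[[j]])
        if (d < min_dist) {
          stop("tag whitelist entries ", i, " and ", j,
               " are at Hamming distance ", d, " (< ", min_dist,
               "); single-error reads would be ambiguous")
        }
      }
    }
  }
  invisible(tags)
}

#' Simulate glycosylation-tag library read pairs with ground truth
#'
#' Emits paired reads for a tag library: R1 carries `barcode + UMI`
#' (error-free unless `barcode_error_rate > 0`), R2 carries the 15-bp tag
#' at `tag_offset` followed by a poly-A tail. Per-cell distinct tag
#' molecules are drawn from a negative binomial with the stage-specific
#' mean `glyco_mean_per_stage`, each base of the emitted tag is substituted
#' independently with probability `tag_error_rate`, and the read emission
#' order is shuffled deterministically so demultiplexing cannot rely on
#' grouping.
#'
#' @param config A [sim_config()].
#' @param tags Optional tag whitelist (pairwise Hamming distance >= 4
#'   enforced); generated from the seed by default.
#' @param cells Optional cell table from [simulate_cells()]; regenerated
#'   from the config otherwise (both generators then share the same cells).
#' @return A list of class `tag_sim` with elements `reads` (tibble
#'   `read_id`, `r1`, `r2`), `tags`, `cells`, and `truth` (list with the
#'   true cell-by-tag UMI count matrix `matrix`, rows in `cells$barcode`
#'   order, plus the long `tag_counts` tibble).
#' @export
simulate_tag_reads <- function(config, tags = NULL, cells = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(tags)) {
    tags <- generate_tag_whitelist(config$n_tags, seed = config$seed,
                                   tag_len = config$tag_len)
  }
  check_tag_whitelist(tags, min_dist = 4L)
  if (is.null(names(tags))) names(tags) <- paste0("tag", seq_along(tags))
  if (is.null(cells)) cells <- simulate_cells(config)

  with_seed(config$seed + 1L, {
    n_cells <- nrow(cells)
    n_mol_per_cell <- stats::rnbinom(
      n_cells, size = 1 / config$dispersion,
      mu = config$glyco_mean_per_stage[cells$stage]
    )
    cell_of_mol <- rep.int(seq_len(n_cells), n_mol_per_cell)
    n_mol <- length(cell_of_mol)
    tag_of_mol <- sample.int(length(tags), n_mol, replace = TRUE)
    umi_of_mol <- random_dna(n_mol, config$umi_len)

    mols <- tibble::tibble(cell = cell_of_mol, tag = tag_of_mol,
                           umi = umi_of_mol)
    # ground truth counts distinct (barcode, UMI, tag) molecules
    mols_d <- dplyr::distinct(mols)
    tag_counts <- dplyr::count(mols_d, .data$cell, .data$tag, name = "count")
    truth_mat <- Matrix::sparseMatrix(
      i = tag_counts$cell, j = tag_counts$tag, x = tag_counts$count,
      dims = c(n_cells, length(tags)),
      dimnames = list(cells$barcode, names(tags))
    )

    # reads: each distinct molecule once, plus Poisson-distributed duplicates
    reps <- 1L + stats::rpois(nrow(mols_d), config$read_dup_rate)
    reads <- mols_d[rep.int(seq_len(nrow(mols_d)), reps), ]
    n_reads <- nrow(reads)

    tag_mat <- seq_char_matrix(unname(tags)[reads$tag], config$tag_len)
    tag_mat <- substitute_bases(tag_mat, config$tag_error_rate)
    tag_seq <- if (n_reads > 0) {
      do.call(paste0, as.data.frame(tag_mat, stringsAsFactors = FALSE))
    } else character(0)

    bc <- cells$barcode[reads$cell]
    if (config$barcode_error_rate > 0 && n_reads > 0) {
      bc_mat <- seq_char_matrix(bc, config$barcode_len)
      bc_mat <- substitute_bases(bc_mat, config$barcode_error_rate)
      bc <- do.call(paste0, as.data.frame(bc_mat, stringsAsFactors = FALSE))
    }

    prefix <- if (config$tag_offset > 0) {
      random_dna(n_reads, config$tag_offset)
    } else ""
    r1 <- paste0(bc, reads$umi)
    r2 <- paste0(prefix, tag_seq, strrep("A", config$polya_len))

    ord <- sample.int(n_reads)
    read_tbl <- tibble::tibble(
      read_id = sprintf("read%07d", seq_len(n_reads)),
      r1 = r1[ord],
      r2 = r2[ord]
    )

    structure(list(
      reads = read_tbl,
      tags = tags,
      cells = cells,
      truth = list(
        matrix = methods::as(truth_mat, "CsparseMatrix"),
        tag_counts = dplyr::mutate(tag_counts,
                                   barcode = cells$barcode[.data$cell],
                                   .before = 1L),
        umi_pairs_per_cell = dplyr::count(
          dplyr::distinct(mols_d, .data$cell, .data$umi),
          .data$cell, name = "n_pairs"
        )
      ),
      config = config
    ), class = "tag_sim")
  })
}

#' Simulate new/old/total count matrix triples with ground truth
#'
#' Total counts per gene are negative binomial around a lognormal baseline
#' scaled so cells average `total_umis_per_cell` transcripts. Stages carry
#' distinct marker-gene programs (fold change `marker_fc` on
#' `marker_frac` of genes per stage) and clusters a smaller program, so
#' cluster-level expression profiles group by stage. Each transcript is
#' labeled "new" independently with the stage's NTR probability (binomial
#' thinning), and `old = total - new` exactly. Genes designated in
#' `config$deg_groups` receive a multiplicative `deg_fold_change`, half
#' elevated in group `a` and half in group `b` so the planted effects do
#' not tilt library sizes (a one-sided tilt would make every other gene
#' shift under total-count normalization); planted gene names and
#' directions are recorded in the truth.
#'
#' @param config A [sim_config()].
#' @param cells Optional cell table from [simulate_cells()].
#' @return A list of class `tri_sim` with elements `new`, `old`, `total`
#'   (sparse cell x gene matrices), `cells`, and `truth` (per-cell true
#'   NTR, planted DEG gene names, marker gene map).
#' @export
simulate_tri_counts <- function(config, cells = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(cells)) cells <- simulate_cells(config)

  with_seed(config$seed + 2L, {
    n_cells <- nrow(cells)
    n_genes <- config$n_genes
    n_mito <- min(config$n_mito_genes, n_genes)
    genes <- c(paste0("MT-", seq_len(n_mito)),
               paste0("G", seq_len(n_genes - n_mito)))

    base_mean <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1)
    base_mean <- base_mean / sum(base_mean) * config$total_umis_per_cell

    # deterministic marker blocks following the mito genes
    n_marker <- round(config$marker_frac * n_genes)
    marker_of_stage <- vector("list", 3L)
    pos <- n_mito
    for (st in 1:3) {
      idx <- seq(pos + 1L, length.out = n_marker)
      idx <- idx[idx <= n_genes]
      marker_of_stage[[st]] <- idx
      pos <- pos + n_marker
    }
    n_cm <- round(config$cluster_marker_frac * n_genes)
    free <- setdiff(seq_len(n_genes), c(seq_len(n_mito), unlist(marker_of_stage)))
    cm_of_cluster <- vector("list", config$n_clusters)
    if (n_cm > 0 && length(free) > 0) {
      for (cl in seq_len(config$n_clusters)) {
        off <- ((cl - 1L) * n_cm) %% length(free)
        cm_of_cluster[[cl]] <- free[(off + seq_len(n_cm) - 1L) %% length(free) + 1L]
      }
    }

    deg_genes <- integer(0)
    if (config$n_deg_genes > 0L) {
      if (is.null(config$deg_groups)) {
        stop("`n_deg_genes` > 0 requires `deg_groups` in the config")
      }
      eligible <- setdiff(free, unlist(cm_of_cluster))
      eligible <- eligible[order(base_mean[eligible], decreasing = TRUE)]
      # plant on well-expressed but not top genes: a fold change on the
      # most abundant genes would shift library sizes enough for
      # total-count normalization to induce compositional shifts in
      # every other gene
      skip <- ceiling(0.1 * length(eligible))
      eligible <- eligible[-seq_len(skip)]
      if (length(eligible) < config$n_deg_genes) {
        stop("not enough eligible genes to plant ", config$n_deg_genes, " DEGs")
      }
      deg_genes <- sort(eligible[seq_len(config$n_deg_genes)])
    }

    mu <- matrix(base_mean, nrow = n_cells, ncol = n_genes, byrow = TRUE)
    for (st in 1:3) {
      rows <- cells$stage == st
      if (any(rows) && length(marker_of_stage[[st]]) > 0) {
        mu[rows, marker_of_stage[[st]]] <-
          mu[rows, marker_of_stage[[st]]] * config$marker_fc
      }
    }
    for (cl in seq_len(config$n_clusters)) {
      rows <- cells$cluster == cl
      if (any(rows) && length(cm_of_cluster[[cl]]) > 0) {
        mu[rows, cm_of_cluster[[cl]]] <-
          mu[rows, cm_of_cluster[[cl]]] * config$cluster_marker_fc
      }
    }
    deg_dir <- character(0)
    if (length(deg_genes) > 0L) {
      # alternate the direction so the planted effects leave library sizes
      # (and hence total-count normalization) balanced between the groups
      deg_dir <- rep(c("up_in_a", "up_in_b"), length.out = length(deg_genes))
      rows_a <- cells$cluster %in% config$deg_groups$a
      rows_b <- cells$cluster %in% config$deg_groups$b
      up_a <- deg_genes[deg_dir == "up_in_a"]
      up_b <- deg_genes[deg_dir == "up_in_b"]
      mu[rows_a, up_a] <- mu[rows_a, up_a] * config$deg_fold_change
      mu[rows_b, up_b] <- mu[rows_b, up_b] * config$deg_fold_change
    }

    total <- matrix(
      stats::rnbinom(n_cells * n_genes, size = 1 / config$dispersion, mu = mu),
      nrow = n_cells, ncol = n_genes
    )
    p_new <- config$ntr_per_stage[cells$stage]
    new <- matrix(
      stats::rbinom(n_cells * n_genes, size = as.vector(total),
                    prob = rep(p_new, times = n_genes)),
      nrow = n_cells, ncol = n_genes
    )
    old <- total - new
    dn <- list(cells$barcode, genes)
    dimnames(total) <- dimnames(new) <- dimnames(old) <- dn

    structure(list(
      new = methods::as(methods::as(new, "sparseMatrix"), "CsparseMatrix"),
      old = methods::as(methods::as(old, "sparseMatrix"), "CsparseMatrix"),
      total = methods::as(methods::as(total, "sparseMatrix"), "CsparseMatrix"),
      cells = cells,
      truth = list(
        ntr_per_cell = tibble::tibble(barcode = cells$barcode,
                                      true_ntr = p_new),
        deg_genes = genes[deg_genes],
        deg_direction = stats::setNames(deg_dir, genes[deg_genes]),
        marker_genes = lapply(marker_of_stage, function(i) genes[i])
      ),
      config = config
    ), class = "tri_sim")
  })
}

#' Simulate an expression matrix with planted quality-control failures
#'
#' Builds a cell-by-gene count matrix where unplanted ("baseline") cells
#' all share the same detected-gene count and total UMI count, so the
#' top-percentile rules have nothing to remove beyond the planted cells,
#' and each planted cell violates exactly one filtering rule:
#' `low_gene` cells express fewer than `thresholds$min_genes` genes,
#' `high_umi` cells carry `high_umi_factor` times the baseline total, and
#' `high_mito` cells place `mito_frac` of their counts on `MT-` genes.
#' Optional `rare` genes are expressed in exactly
#' `thresholds$min_cells_per_gene - 1` surviving cells so the gene rule
#' removes exactly them.
#'
#' @param n_cells Number of baseline cells.
#' @param n_genes Number of ordinary genes (excluding rare genes).
#' @param n_low_gene,n_high_umi,n_high_mito Planted cell counts per rule.
#' @param n_rare_genes Planted genes below the cells-per-gene threshold.
#' @param genes_per_cell,umis_per_cell Baseline detected genes and total
#'   UMIs per cell (identical across baseline cells by construction).
#' @param low_gene_count Detected genes in planted low-gene cells.
#' @param high_umi_factor Total-UMI multiplier for planted high-UMI cells.
#' @param mito_frac Mitochondrial count fraction for planted high-mito
#'   cells (must exceed `thresholds$max_mito_pct / 100`).
#' @param n_mito_genes Genes named with the `MT-` prefix.
#' @param thresholds A [qc_thresholds()] the truth table is computed for.
#' @param seed Integer seed.
#' @return A list of class `qc_sim`: `counts` (sparse matrix), and truth
#'   tibbles `truth_cells` (`cell`, `planted`, `rule`, `survives`) and
#'   `truth_genes` (`gene`, `planted`, `survives`).
#' @export
simulate_expression_for_qc <- function(n_cells = 100L, n_genes = 400L,
                                       n_low_gene = 2L, n_high_umi = 2L,
                                       n_high_mito = 1L, n_rare_genes = 2L,
                                       genes_per_cell = 250L,
                                       umis_per_cell = 1000L,
                                       low_gene_count = 50L,
                                       high_umi_factor = 10,
                                       mito_frac = 0.25,
                                       n_mito_genes = 10L,
                                       thresholds = qc_thresholds(),
                                       seed = 1L) {
  stopifnot(genes_per_cell <= n_genes - n_mito_genes,
            low_gene_count < thresholds$min_genes,
            mito_frac > thresholds$max_mito_pct / 100)
  n_total <- n_cells + n_low_gene + n_high_umi + n_high_mito
  # after the gene-count rule removes the low-gene cells, the top-UMI rule
  # must be able to isolate the planted high-UMI cells
  m <- n_total - n_low_gene
  if (n_high_umi > m - ceiling((100 - thresholds$top_umi_pct) / 100 * m)) {
    stop("too many high-UMI cells for the top-", thresholds$top_umi_pct,
         "% rule to isolate; increase n_cells")
  }

  with_seed(seed, {
    normal_genes <- paste0("G", seq_len(n_genes - n_mito_genes))
    mito_genes <- paste0("MT-", seq_len(n_mito_genes))
    rare_genes <- if (n_rare_genes > 0) paste0("RARE", seq_len(n_rare_genes)) else character(0)
    genes <- c(mito_genes, normal_genes, rare_genes)

    cell_ids <- sprintf("cell%04d", seq_len(n_total))
    type <- c(rep("baseline", n_cells), rep("low_gene", n_low_gene),
              rep("high_umi", n_high_umi), rep("high_mito", n_high_mito))

    # rare genes live in min_cells_per_gene - 1 distinct baseline host cells
    n_host_per_gene <- thresholds$min_cells_per_gene - 1L
    n_hosts <- n_rare_genes * n_host_per_gene
    stopifnot(n_hosts <= n_cells)
    host_of_rare <- if (n_rare_genes > 0) {
      split(seq_len(n_hosts), rep(seq_len(n_rare_genes), each = n_host_per_gene))
    } else list()
    hosted <- integer(n_total)
    for (rg in seq_along(host_of_rare)) hosted[host_of_rare[[rg]]] <- hosted[host_of_rare[[rg]]] + 1L

    spread <- function(total, k) {
      base <- total %/% k
      rep(base, k) + c(rep(1L, total - base * k), rep(0L, k - (total - base * k)))
    }

    build_cell <- function(i) {
      if (type[i] == "low_gene") {
        g <- sample(normal_genes, low_gene_count)
        tot <- round(umis_per_cell * low_gene_count / genes_per_cell)
        return(list(genes = g, counts = spread(tot, low_gene_count)))
      }
      if (type[i] == "high_umi") {
        g <- sample(normal_genes, genes_per_cell)
        return(list(genes = g,
                    counts = spread(as.integer(high_umi_factor * umis_per_cell),
                                    genes_per_cell)))
      }
      if (type[i] == "high_mito") {
        mito_tot <- as.integer(round(mito_frac * umis_per_cell))
        k <- genes_per_cell - n_mito_genes
        g <- sample(normal_genes, k)
        return(list(genes = c(mito_genes, g),
                    counts = c(spread(mito_tot, n_mito_genes),
                               spread(umis_per_cell - mito_tot, k))))
      }
      # baseline, possibly hosting rare genes
      k <- genes_per_cell - hosted[i]
      g <- sample(normal_genes, k)
      list(genes = g, counts = spread(umis_per_cell - hosted[i], k))
    }

    for (attempt in 1:20) {
      parts <- lapply(seq_len(n_total), build_cell)
      i_idx <- rep.int(seq_len(n_total), vapply(parts, function(p) length(p$genes), integer(1)))
      j_gene <- unlist(lapply(parts, `[[`, "genes"), use.names = FALSE)
      x_cnt <- unlist(lapply(parts, `[[`, "counts"), use.names = FALSE)
      if (n_rare_genes > 0) {
        for (rg in seq_len(n_rare_genes)) {
          i_idx <- c(i_idx, host_of_rare[[rg]])
          j_gene <- c(j_gene, rep(rare_genes[rg], n_host_per_gene))
          x_cnt <- c(x_cnt, rep(1L, n_host_per_gene))
        }
      }
      counts <- Matrix::sparseMatrix(
        i = i_idx, j = match(j_gene, genes), x = x_cnt,
        dims = c(n_total, length(genes)), dimnames = list(cell_ids, genes)
      )
      surviving <- type == "baseline"
      cover <- Matrix::colSums(counts[surviving, , drop = FALSE] > 0)
      ok <- all(cover[c(mito_genes, normal_genes)] == 0 |
                  cover[c(mito_genes, normal_genes)] >= thresholds$min_cells_per_gene)
      if (ok) break
      if (attempt == 20) stop("could not place genes so that every baseline gene meets the cells-per-gene rule")
    }

    rule <- c(baseline = NA_character_, low_gene = "min_genes",
              high_umi = "top_umi_pct", high_mito = "max_mito_pct")[type]
    truth_cells <- tibble::tibble(
      cell = cell_ids, planted = type, rule = unname(rule),
      survives = type == "baseline"
    )
    cover_all <- Matrix::colSums(counts[surviving, , drop = FALSE] > 0)
    truth_genes <- tibble::tibble(
      gene = genes,
      planted = genes %in% rare_genes,
      survives = unname(cover_all >= thresholds$min_cells_per_gene)
    )

    structure(list(counts = counts, truth_cells = truth_cells,
                   truth_genes = truth_genes, thresholds = thresholds,
                   seed = seed),
              class = "qc_sim")
  })
}
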