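test_that("qc_filter removes exactly the planted violations from the fixture", {
  sim <- simulate_expression_for_qc(n_cells = 100, n_low_gene = 2,
                                    n_high_umi = 2, n_high_mito = 1,
                                    n_rare_genes = 2, seed = 5)
  res <- qc_filter(sim$counts, sim$thresholds)
  tr <- sim$truth_cells
  expect_setequal(rownames(res$matrix), tr$cell[tr$survives])
  r <- res$report
  expect_setequal(r$removed_min_or_top_genes, tr$cell[tr$rule %in% "min_genes"])
  expect_setequal(r$removed_top_umi, tr$cell[tr$rule %in% "top_umi_pct"])
  expect_setequal(r$removed_mito, tr$cell[tr$rule %in% "max_mito_pct"])
  tg <- sim$truth_genes
  expect_setequal(colnames(res$matrix), tg$gene[tg$survives])
  expect_true(all(tg$gene[tg$planted] %in% r$removed_genes))
  # removed + retained partitions the input on both axes
  expect_equal(length(r$removed_min_or_top_genes) + length(r$removed_top_umi) +
                 length(r$removed_mito) + nrow(res$matrix), nrow(sim$counts))
  expect_equal(length(r$removed_genes) + ncol(res$matrix), ncol(sim$counts))
})

test_that("a 25% mitochondrial cell is excluded by the 20% rule", {
  sim <- simulate_expression_for_qc(n_cells = 60, n_low_gene = 0,
                                    n_high_umi = 0, n_high_mito = 1,
                                    n_rare_genes = 0, mito_frac = 0.25,
                                    seed = 3)
  res <- qc_filter(sim$counts, sim$thresholds)
  bad <- sim$truth_cells$cell[sim$truth_cells$planted == "high_mito"]
  expect_equal(res$report$removed_mito, bad)
  expect_false(bad %in% rownames(res$matrix))
})

test_that("genes expressed in fewer than 5 retained cells are dropped", {
  counts <- Matrix::Matrix(matrix(5, nrow = 10, ncol = 3), sparse = TRUE)
  dimnames(counts) <- list(sprintf("c%d", 1:10), c("g1", "g2", "g3"))
  counts[5:10, 2] <- 0   # g2 expressed in 4 cells
  th <- qc_thresholds(min_genes = 1)
  res <- qc_filter(counts, th)
  expect_equal(res$report$removed_genes, "g2")
  expect_true(all(c("g1", "g3") %in% colnames(res$matrix)))
})

test_that("lognormalize matches direct arithmetic and is scale-invariant per cell", {
  m <- Matrix::Matrix(matrix(c(10, 0, 10,
                               4, 4, 0), nrow = 2, byrow = TRUE), sparse = TRUE)
  dimnames(m) <- list(c("c1", "c2"), c("g1", "g2", "g3"))
  norm <- lognormalize(m)
  expect_equal(norm["c1", ], c(g1 = log(5001), g2 = 0, g3 = log(5001)))
  doubled <- lognormalize(2 * m)
  expect_equal(as.matrix(doubled), as.matrix(norm))
  zero_gene <- Matrix::Matrix(cbind(as.matrix(m), g4 = c(0, 0)), sparse = TRUE)
  expect_equal(unname(as.matrix(lognormalize(zero_gene))[, 4]), c(0, 0))
  empty <- m; empty[1, ] <- 0
  expect_error(lognormalize(empty), "zero total")
})

test_that("wilcoxon exact p matches full-enumeration oracle on random small cases", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p.value, 0.1)
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(1, 2))$p.value, 1)
  expect_equal(wilcoxon_rank_sum(rep(3, 4), rep(3, 5))$p.value, 1)
  set.seed(17)
  for (i in 1:200) {
    na <- sample(1:6, 1); nb <- sample(1:6, 1)
    vals <- if (i %% 2 == 0) sample(1:4, na + nb, replace = TRUE) else rnorm(na + nb)
    a <- vals[seq_len(na)]; b <- vals[-seq_len(na)]
    expect_equal(wilcoxon_rank_sum(a, b)$p.value, oracle_wilcoxon_p(a, b),
                 tolerance = 1e-12)
  }
})

test_that("wilcoxon normal approximation tracks the exact tail and wilcox.test", {
  set.seed(19)
  for (i in 1:25) {
    a <- rnorm(6); b <- rnorm(6) + runif(1, -1, 1)
    exact <- wilcoxon_rank_sum(a, b)$p.value
    approx <- wilcoxon_rank_sum(a, b, exact_max = 0)$p.value
    expect_lt(abs(exact - approx), 0.02)
  }
  for (i in 1:10) {
    a <- rnorm(40); b <- rnorm(35) + 0.3
    got <- wilcoxon_rank_sum(a, b)
    ref <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                               correct = TRUE))
    expect_equal(got$p.value, unname(ref$p.value), tolerance = 1e-10)
    expect_equal(got$statistic, unname(ref$statistic))
  }
  # invariance under strictly increasing transforms of the pooled data
  a <- rnorm(20); b <- rnorm(20) + 1
  expect_equal(wilcoxon_rank_sum(a, b)$p.value,
               wilcoxon_rank_sum(exp(a), exp(b))$p.value)
})

make_deg_fixture <- function() {
  cfg <- sim_config(n_samples = 3L, clusters_per_sample = 1L,
                    n_cells_per_sample = 200L, n_genes = 2000L,
                    cluster_mix = 1, marker_frac = 0,
                    cluster_marker_frac = 0,
                    ntr_per_stage = c(0.3, 0.3, 0.3),
                    n_deg_genes = 50L, deg_fold_change = 2,
                    deg_groups = list(a = 1L, b = 2L), seed = 23L)
  sim <- simulate_tri_counts(cfg)
  norm <- lognormalize(sim$total)
  list(cfg = cfg, sim = sim, norm = norm,
       a = sim$cells$barcode[sim$cells$cluster == 1L],
       b = sim$cells$barcode[sim$cells$cluster == 2L])
}

test_that("DEG procedure recovers planted fold changes with Bonferroni control", {
  fx <- make_deg_fixture()
  deg <- find_degs(fx$norm, fx$a, fx$b)
  hits <- deg$gene[deg$significant]
  planted <- fx$sim$truth$deg_genes
  sens <- mean(planted %in% hits)
  expect_gte(sens, 0.9)
  expect_lte(length(setdiff(hits, planted)), 1)
  expect_true(all(deg$p_adj >= deg$p_raw - 1e-15))
  expect_equal(deg$p_adj, pmin(1, deg$p_raw * attr(deg, "n_tested")))
})

test_that("filters and label swap behave per the significance contract", {
  fx <- make_deg_fixture()
  deg <- find_degs(fx$norm, fx$a, fx$b)
  # nothing below the pct or logFC thresholds is ever significant
  expect_true(all(pmax(deg$pct_1, deg$pct_2)[deg$significant] > 0.10))
  expect_true(all(abs(deg$avg_logFC[deg$significant]) > 0.25))
  # swapping groups flips logFC and preserves p exactly
  swapped <- find_degs(fx$norm, fx$b, fx$a)
  common <- intersect(deg$gene, swapped$gene)
  expect_equal(swapped$avg_logFC[match(common, swapped$gene)],
               -deg$avg_logFC[match(common, deg$gene)])
  expect_equal(swapped$p_raw[match(common, swapped$gene)],
               deg$p_raw[match(common, deg$gene)])
  # identical expression in both groups: no gene passes the logFC filter
  null_deg <- find_degs(fx$norm, fx$a[1:50], fx$a[51:100])
  expect_equal(sum(null_deg$significant), 0)
  expect_error(find_degs(fx$norm, fx$a, fx$a), "disjoint")
})

test_that("genes under the 10% expression-fraction rule are not tested", {
  set.seed(31)
  n <- 40
  m <- Matrix::Matrix(0, nrow = 2 * n, ncol = 2, sparse = TRUE,
                      dimnames = list(sprintf("c%d", 1:(2 * n)), c("rare", "common")))
  m[sample(2 * n, 3), "rare"] <- 5       # ~4% of cells
  m[, "common"] <- rpois(2 * n, 5) + 1
  norm <- lognormalize(m)
  deg <- find_degs(norm, 1:n, (n + 1):(2 * n), logfc_threshold = 0)
  expect_false("rare" %in% deg$gene)
})
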