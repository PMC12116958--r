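small_cfg <- function(...) {
  sim_config(n_cells_per_sample = 40L, n_genes = 80L, ...)
}

test_that("config validation rejects bad counts, probabilities and maps", {
  expect_error(sim_config(n_cells_per_sample = 0), "positive")
  expect_error(sim_config(tag_error_rate = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(ntr_per_stage = c(0.5, 0.2, 1.2)), "\\[0, 1\\]")
  expect_error(sim_config(tag_len = 14), "fixed at 15")
  expect_error(sim_config(stage_of_cluster = rep(4L, 18)), "stage in \\{1,2,3\\}")
  expect_error(sim_config(deg_groups = list(a = 1, b = 1)), "disjoint")
})

test_that("default stage effects encode the study orderings", {
  cfg <- sim_config()
  g <- cfg$glyco_mean_per_stage
  expect_true(g[2] > g[3] && g[3] > g[1])
  n <- cfg$ntr_per_stage
  expect_true(n[3] > n[1] && n[1] > n[2])
})

test_that("error-free tag reads reproduce their source tag exactly", {
  cfg <- small_cfg(tag_error_rate = 0)
  sim <- simulate_tag_reads(cfg)
  obs <- substr(sim$reads$r2, 1, 15)
  expect_true(all(obs %in% sim$tags))
})

test_that("tag read generation is deterministic and FASTQ output byte-identical", {
  cfg <- small_cfg()
  s1 <- simulate_tag_reads(cfg)
  s2 <- simulate_tag_reads(cfg)
  expect_identical(s1$reads, s2$reads)

  d <- withr::local_tempdir()
  f1 <- file.path(d, c("a_R1.fastq", "a_R2.fastq"))
  f2 <- file.path(d, c("b_R1.fastq", "b_R2.fastq"))
  write_tag_fastq(s1, f1[1], f1[2])
  write_tag_fastq(s2, f2[1], f2[2])
  expect_identical(readBin(f1[1], "raw", file.size(f1[1])),
                   readBin(f2[1], "raw", file.size(f2[1])))
  expect_identical(readBin(f1[2], "raw", file.size(f1[2])),
                   readBin(f2[2], "raw", file.size(f2[2])))
})

test_that("tag whitelists closer than Hamming distance 4 are rejected", {
  bad <- c("AAAAAAAAAAAAAAA", "AAAAAAAAAAAAACC")
  expect_error(simulate_tag_reads(small_cfg(), tags = bad), "ambiguous")
  wl <- generate_tag_whitelist(6, seed = 42)
  d <- outer(wl, wl, Vectorize(function(x, y) hamming(x, y)))
  expect_true(all(d[upper.tri(d)] >= 4))
})

test_that("per-base substitution rate matches its closed-form distance distribution", {
  p <- 0.01
  cfg <- sim_config(n_cells_per_sample = 350L, tag_error_rate = p,
                    glyco_mean_per_stage = c(50, 50, 50), seed = 7L)
  sim <- simulate_tag_reads(cfg)
  dm <- demultiplex(sim$reads, barcode_policy(), sim$tags,
                    cell_whitelist = sim$cells$barcode)
  n <- dm$report$reads_seen
  expect_gt(n, 90000)
  expected <- (1 - p)^15 + 15 * p * (1 - p)^14
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(dm$report$valid / n - expected), 3 * se)
})

test_that("ground-truth tag counts equal distinct (barcode, UMI) pairs", {
  cfg <- small_cfg(read_dup_rate = 0.5)
  sim <- simulate_tag_reads(cfg)
  per_cell_truth <- Matrix::rowSums(sim$truth$matrix)
  pairs <- sim$truth$umi_pairs_per_cell
  got <- numeric(nrow(sim$cells))
  got[pairs$cell] <- pairs$n_pairs
  # distinct (barcode, UMI) pairs can be fewer than (barcode, UMI, tag)
  # triples only if one UMI recurs across tags in a cell; equality holds
  # when UMIs are unique within the cell, and can never exceed
  expect_true(all(got <= per_cell_truth))
  expect_true(all(Matrix::rowSums(sim$truth$matrix) >= got))
  # every emitted read's true barcode is a simulated cell
  bc <- substr(sim$reads$r1, 1, cfg$barcode_len)
  expect_true(all(bc %in% sim$cells$barcode))
})

test_that("tri-count matrices conserve new + old = total with stage NTR", {
  cfg <- small_cfg()
  sim <- simulate_tri_counts(cfg)
  expect_equal(sim$new + sim$old, sim$total)
  expect_true(all(sim$new@x >= 0), all(sim$old@x >= 0))

  all_new <- simulate_tri_counts(small_cfg(ntr_per_stage = c(1, 1, 1)))
  expect_equal(all_new$new, all_new$total)
  expect_equal(Matrix::nnzero(all_new$old), 0)

  none_new <- simulate_tri_counts(small_cfg(ntr_per_stage = c(0, 0, 0)))
  expect_equal(Matrix::nnzero(none_new$new), 0)
  expect_equal(none_new$old, none_new$total)
})

test_that("observed per-cell NTR stays within binomial error of its target", {
  cfg <- sim_config(n_samples = 3L, clusters_per_sample = 1L,
                    n_cells_per_sample = 5L, n_genes = 200L,
                    ntr_per_stage = c(0.3, 0.3, 0.3),
                    total_umis_per_cell = 10000, cluster_mix = 1)
  sim <- simulate_tri_counts(cfg)
  tot <- Matrix::rowSums(sim$total)
  obs <- Matrix::rowSums(sim$new) / tot
  sd3 <- 3 * sqrt(0.3 * 0.7 / tot)
  expect_true(all(abs(obs - 0.3) < sd3))
})

test_that("simulated group means reproduce the configured stage orderings", {
  cfg <- sim_config(n_cells_per_sample = 500L, n_genes = 150L, seed = 11L)
  cells <- simulate_cells(cfg)
  tags <- simulate_tag_reads(cfg, cells = cells)
  glyco_mean <- tapply(Matrix::rowSums(tags$truth$matrix), cells$stage, mean)
  expect_true(glyco_mean[2] > glyco_mean[3] && glyco_mean[3] > glyco_mean[1])
  tri <- simulate_tri_counts(cfg, cells = cells)
  ntr <- Matrix::rowSums(tri$new) / Matrix::rowSums(tri$total)
  ntr_mean <- tapply(ntr, cells$stage, mean)
  expect_true(ntr_mean[3] > ntr_mean[1] && ntr_mean[1] > ntr_mean[2])
})

test_that("QC fixture plants exactly one violation per cell and a clean truth table", {
  sim <- simulate_expression_for_qc(n_cells = 100, n_low_gene = 2,
                                    n_high_umi = 2, n_high_mito = 1,
                                    n_rare_genes = 2, seed = 5)
  tr <- sim$truth_cells
  expect_equal(sum(!tr$survives), 5)
  expect_equal(unname(table(tr$rule)[c("min_genes", "top_umi_pct", "max_mito_pct")]),
               c(2L, 2L, 1L), ignore_attr = TRUE)
  th <- sim$thresholds
  gpc <- Matrix::rowSums(sim$counts > 0)
  # enumerate the absolute rules directly from the matrix
  low <- gpc < th$min_genes
  expect_equal(sim$truth_cells$cell[low], tr$cell[tr$rule %in% "min_genes"])
  mito <- Matrix::rowSums(sim$counts[, grep("^MT-", colnames(sim$counts)), drop = FALSE])
  high_mito <- 100 * mito / Matrix::rowSums(sim$counts) > th$max_mito_pct
  expect_equal(sim$truth_cells$cell[high_mito], tr$cell[tr$rule %in% "max_mito_pct"])
  # planted-free fixture: everything survives the absolute rules
  clean <- simulate_expression_for_qc(n_cells = 60, n_low_gene = 0,
                                      n_high_umi = 0, n_high_mito = 0,
                                      n_rare_genes = 0, seed = 2)
  expect_true(all(clean$truth_cells$survives))
})
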