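test_that("hamming counts mismatches and treats N as matching nothing", {
  expect_equal(hamming("ACGTA", "ACGTA"), 0L)
  expect_equal(hamming("ACGTA", "ACGTT"), 1L)
  expect_equal(hamming("NNNNN", "ACGTA"), 5L)
  expect_equal(hamming("NNNNN", "NNNNN"), 5L)
  expect_equal(hamming(c("AA", "AC"), "AA"), c(0L, 1L))
  expect_error(hamming("ACG", "AC"), "equal-length")
})

test_that("match_tag applies the distance-below-2 validity rule", {
  wl <- unname(toy_tags)
  expect_equal(match_tag(wl[2], wl), 2L)
  expect_equal(match_tag(mutate_seq(wl[1], 3, "G"), wl), 1L)
  expect_true(is.na(match_tag(mutate_seq(wl[1], c(3, 9), c("G", "C")), wl)))
  # one N still validates (distance 1), two N's never can
  expect_equal(match_tag(mutate_seq(wl[4], 5, "N"), wl), 4L)
  expect_true(is.na(match_tag(mutate_seq(wl[4], c(5, 6), "N"), wl)))
  # equidistant between two close tags -> ambiguous sentinel
  close_wl <- c("AAAAAAAAAAAAAAA", "AAAAAAAAAAAAACC")
  expect_equal(match_tag("AAAAAAAAAAAAAAC", close_wl), 0L)
})

test_that("hash-map matching agrees with brute-force scanning", {
  set.seed(21)
  wl <- generate_tag_whitelist(4, seed = 3)
  obs <- character(300)
  for (i in seq_along(obs)) {
    base <- sample(unname(wl), 1)
    nmut <- sample(0:3, 1)
    pos <- sample(15, nmut)
    obs[i] <- mutate_seq(base, pos, sample(c("A", "C", "G", "T", "N"),
                                           nmut, replace = TRUE))
  }
  map <- glycodyn:::build_h1_map(unname(wl))
  got <- glycodyn:::h1_lookup(obs, map)
  expect_equal(unname(got), oracle_match_tag(obs, unname(wl)))
  expect_equal(unname(match_tag(obs, unname(wl))),
               oracle_match_tag(obs, unname(wl)))
})

test_that("barcode and UMI extraction slices positionally and flags short reads", {
  pol <- barcode_policy(barcode_len = 16, umi_len = 12)
  r1 <- paste0(strrep("A", 16), strrep("C", 12))
  out <- extract_barcode_umi(c(r1, "ACGT"), pol)
  expect_equal(out$barcode[1], strrep("A", 16))
  expect_equal(out$umi[1], strrep("C", 12))
  expect_true(is.na(out$barcode[2]) && is.na(out$umi[2]))
  # N passes through untouched for the correction stage
  r1n <- paste0("N", strrep("A", 15), strrep("C", 12))
  expect_equal(extract_barcode_umi(r1n, pol)$barcode[1],
               paste0("N", strrep("A", 15)))
})

test_that("barcode correction returns unique Hamming-1 matches only", {
  wl <- c("AAAA", "CCCC", "AACC")
  expect_equal(correct_barcode("AAAA", wl), "AAAA")
  expect_equal(correct_barcode("AAAT", wl), "AAAA")
  expect_equal(correct_barcode("NAAA", wl), "AAAA")
  # distance 1 from both AAAA and AACC -> unassigned
  expect_true(is.na(correct_barcode("AAAC", wl)))
  expect_true(is.na(correct_barcode("GGGG", wl)))
  # exhaustive check on the toy whitelist: every 1-substitution variant
  # either corrects to its source or is ambiguous per brute force
  for (src in wl) {
    for (pos in 1:4) {
      for (sub in setdiff(c("A", "C", "G", "T"), substr(src, pos, pos))) {
        v <- mutate_seq(src, pos, sub)
        d <- vapply(wl, function(w) hamming(v, w), integer(1))
        expected <- if (sum(d <= 1) == 1) wl[which(d <= 1)] else NA_character_
        expect_identical(correct_barcode(v, wl), unname(expected))
      }
    }
  }
})

test_that("poly-A trimming removes the suffix from the first long A-run", {
  expect_equal(trim_polya("ACGTAAAAAAA"), "ACGT")
  expect_equal(trim_polya("ACGTACGT"), "ACGTACGT")
  expect_equal(trim_polya("AAAAAA"), "")
  expect_equal(trim_polya("ACGAAAAAACGTAAAAAA"), "ACG")
  expect_equal(trim_polya("ACGTAAAA", min_run = 4), "ACGT")
})

test_that("demultiplexing error-free reads reproduces ground truth exactly", {
  cfg <- sim_config(n_cells_per_sample = 40L)
  sim <- simulate_tag_reads(cfg)
  dm <- demultiplex(sim$reads, barcode_policy(), sim$tags,
                    cell_whitelist = sim$cells$barcode)
  expect_equal(as.matrix(dm$matrix), as.matrix(sim$truth$matrix))
  r <- dm$report
  expect_equal(r$valid, r$reads_seen)
  expect_equal(r$invalid + r$ambiguous + r$unassigned + r$skipped, 0)
})

test_that("duplicate (barcode, UMI, tag) reads are counted once", {
  pol <- barcode_policy(barcode_len = 4, umi_len = 3, tag_offset = 0)
  wl <- unname(toy_tags)
  reads <- tibble::tibble(
    read_id = sprintf("r%d", 1:4),
    r1 = c("AAAACCC", "AAAACCC", "AAAACCC", "AAAAGGG"),
    r2 = paste0(wl[1], strrep("A", 10))
  )
  dm <- demultiplex(reads, pol, wl)
  expect_equal(sum(dm$matrix), 2)  # two distinct UMIs
  expect_equal(dm$report$valid, 4)
})

test_that("reads at tag distance 2 are excluded and tallied invalid", {
  pol <- barcode_policy(barcode_len = 4, umi_len = 3)
  wl <- unname(toy_tags)
  bad_tag <- mutate_seq(wl[1], c(2, 9), c("C", "G"))
  reads <- tibble::tibble(
    read_id = c("r1", "r2"),
    r1 = c("AAAACCC", "AAAAGGG"),
    r2 = c(paste0(wl[1], "AAAAAA"), paste0(bad_tag, "AAAAAA"))
  )
  dm <- demultiplex(reads, pol, wl)
  expect_equal(dm$report$invalid, 1)
  expect_equal(dm$report$valid, 1)
  expect_equal(sum(dm$matrix), 1)
})

test_that("tally partitions reads exactly and order does not matter", {
  cfg <- sim_config(n_cells_per_sample = 30L, tag_error_rate = 0.05,
                    barcode_error_rate = 0.01, seed = 9L)
  sim <- simulate_tag_reads(cfg)
  dm <- demultiplex(sim$reads, barcode_policy(), sim$tags,
                    cell_whitelist = sim$cells$barcode)
  r <- dm$report
  expect_equal(r$valid + r$invalid + r$ambiguous + r$unassigned + r$skipped,
               r$reads_seen)
  expect_lte(sum(dm$matrix), r$valid)
  shuffled <- sim$reads[rev(seq_len(nrow(sim$reads))), ]
  dm2 <- demultiplex(shuffled, barcode_policy(), sim$tags,
                     cell_whitelist = sim$cells$barcode)
  expect_equal(dm2$matrix, dm$matrix)
  expect_equal(dm2$report, dm$report)
})

test_that("FASTQ streaming demux matches in-memory demux across chunks", {
  cfg <- sim_config(n_cells_per_sample = 30L, tag_error_rate = 0.02, seed = 4L)
  sim <- simulate_tag_reads(cfg)
  d <- withr::local_tempdir()
  fq <- file.path(d, c("R1.fastq.gz", "R2.fastq.gz"))
  write_tag_fastq(sim, fq[1], fq[2])
  dm_mem <- demultiplex(sim$reads, barcode_policy(), sim$tags,
                        cell_whitelist = sim$cells$barcode)
  dm_fq <- demultiplex_fastq(fq[1], fq[2], barcode_policy(), sim$tags,
                             cell_whitelist = sim$cells$barcode,
                             chunk_size = 997L)
  expect_equal(dm_fq$matrix, dm_mem$matrix)
  expect_equal(dm_fq$report, dm_mem$report)
})

test_that("malformed FASTQ input raises a located error", {
  d <- withr::local_tempdir()
  bad <- file.path(d, "bad.fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "not a record"), bad)
  expect_error(
    demultiplex_fastq(bad, bad, barcode_policy(2, 2), unname(toy_tags)),
    "malformed FASTQ"
  )
})
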