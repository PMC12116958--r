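#' Hamming distance between equal-length sequences
#'
#' Counts mismatched positions. `N` mismatches every base, including `N`
#' itself, so an ambiguous base can never contribute a match.
#'
#' @param a,b Character vectors of sequences; recycled elementwise, every
#'   compared pair must have equal length.
#' @return Integer vector of distances.
#' @examples
#' hamming("ACGTA", "ACGTT")
#' hamming("NNNNN", "ACGTA")
#' @export
hamming <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  if (any(nchar(a) != nchar(b))) {
    stop("hamming() requires equal-length sequences")
  }
  vapply(seq_len(n), function(i) {
    ca <- strsplit(a[[i]], "", fixed = TRUE)[[1L]]
    cb <- strsplit(b[[i]], "", fixed = TRUE)[[1L]]
    sum(!(ca == cb & ca != "N" & cb != "N"))
  }, integer(1))
}

# Lookup table mapping every sequence within Hamming distance 1 of a
# whitelist entry (substitutions over A/C/G/T/N) to its entry index, with
# collisions marked ambiguous. Contract identical to brute-force scanning,
# but a single hash lookup per observed sequence.
build_h1_map <- function(whitelist, alphabet = c(DNA_BASES, "N")) {
  keys <- character(0)
  vals <- integer(0)
  for (i in seq_along(whitelist)) {
    w <- whitelist[[i]]
    chars <- strsplit(w, "", fixed = TRUE)[[1L]]
    nb <- w
    for (pos in seq_along(chars)) {
      for (sub in setdiff(alphabet, chars[[pos]])) {
        tmp <- chars
        tmp[[pos]] <- sub
        nb <- c(nb, paste(tmp, collapse = ""))
      }
    }
    keys <- c(keys, unique(nb))
    vals <- c(vals, rep.int(i, length(unique(nb))))
  }
  # a key reachable from two different entries is ambiguous (value 0);
  # an exact whitelist sequence always wins over being a neighbor of another
  exact <- match(keys, whitelist)
  dup_first <- !duplicated(keys)
  amb <- keys %in% keys[duplicated(keys)]
  vals[amb & is.na(exact)] <- 0L
  vals[!is.na(exact)] <- exact[!is.na(exact)]
  list(keys = keys[dup_first], vals = vals[dup_first])
}

h1_lookup <- function(observed, map) {
  idx <- match(observed, map$keys)
  out <- map$vals[idx]      # NA = no entry within distance 1
  out
}

#' Match an observed 15-mer against a tag whitelist
#'
#' Implements the distance-below-2 validity rule: the unique whitelist tag
#' at Hamming distance <= 1 is returned; a read at distance 2 or more from
#' every tag is invalid. With two or more tags tying at the minimal
#' distance <= 1 (only possible when whitelist tags are closer than
#' distance 3 to each other) the call is ambiguous.
#'
#' @param observed Character vector of observed tag sequences (length 15).
#' @param whitelist Character vector of tag sequences.
#' @return Integer vector of whitelist indices, with `NA` for invalid
#'   reads and `0` for ambiguous ones.
#' @examples
#' wl <- c("AAAAAAAAAAAAAAA", "CCCCCCCCCCCCCCC")
#' match_tag("AAAAAAAAAAAAAAT", wl)  # distance 1 -> tag 1
#' match_tag("AAAAAAAAAAAAATT", wl)  # distance 2 -> invalid (NA)
#' @export
match_tag <- function(observed, whitelist) {
  stopifnot(length(whitelist) >= 1L)
  tag_len <- nchar(whitelist[[1L]])
  if (any(nchar(whitelist) != tag_len)) {
    stop("whitelist tags must share one length")
  }
  if (any(nchar(observed) != tag_len)) {
    stop("observed sequences must have the whitelist tag length (", tag_len, ")")
  }
  d <- vapply(whitelist, function(w) hamming(observed, w), integer(length(observed)))
  d <- matrix(d, nrow = length(observed))
  dmin <- apply(d, 1L, min)
  nmin <- rowSums(d == dmin)
  out <- apply(d, 1L, which.min)
  out[dmin > 1L] <- NA_integer_
  out[dmin <= 1L & nmin > 1L] <- 0L
  as.integer(out)
}

#' Extract cell barcode and UMI from R1 sequences
#'
#' The barcode is the first `barcode_len` bases of R1 and the UMI the next
#' `umi_len` bases (0-based, half-open slicing). Reads too short for the
#' policy yield `NA` in both columns.
#'
#' @param r1 Character vector of R1 sequences.
#' @param policy A [barcode_policy()].
#' @return Tibble with columns `barcode` and `umi`.
#' @export
extract_barcode_umi <- function(r1, policy = barcode_policy()) {
  need <- policy$barcode_len + policy$umi_len
  short <- nchar(r1) < need
  bc <- substr(r1, 1L, policy$barcode_len)
  umi <- substr(r1, policy$barcode_len + 1L, need)
  bc[short] <- NA_character_
  umi[short] <- NA_character_
  tibble::tibble(barcode = bc, umi = umi)
}

#' Correct cell barcodes against a whitelist
#'
#' An exact whitelist match is kept as-is; otherwise the unique whitelist
#' entry at Hamming distance 1 is substituted. Barcodes with no candidate,
#' or equidistant from two or more entries, are unassigned (`NA`).
#'
#' @param barcodes Character vector of observed barcodes.
#' @param whitelist Character vector of known cell barcodes (uniform
#'   length, non-empty).
#' @return Character vector of corrected barcodes with `NA` where
#'   unassignable.
#' @export
correct_barcode <- function(barcodes, whitelist) {
  if (length(whitelist) == 0L) stop("cell-barcode whitelist is empty")
  if (length(unique(nchar(whitelist))) != 1L) {
    stop("cell-barcode whitelist entries must share one length")
  }
  map <- build_h1_map(whitelist)
  idx <- h1_lookup(barcodes, map)
  out <- ifelse(is.na(idx) | idx == 0L, NA_character_, whitelist[pmax(idx, 1L)])
  out[nchar(barcodes) != nchar(whitelist[[1L]])] <- NA_character_
  out
}

#' Trim a poly-A tail
#'
#' Removes the suffix beginning at the first run of at least `min_run`
#' consecutive `A`s; sequences without such a run are unchanged.
#'
#' @param seq Character vector of sequences.
#' @param min_run Minimum run length that counts as a tail (default 6).
#' @return Trimmed sequences.
#' @examples
#' trim_polya("ACGTAAAAAAA")  # "ACGT"
#' @export
trim_polya <- function(seq, min_run = 6L) {
  pat <- sprintf("A{%d,}", min_run)
  pos <- regexpr(pat, seq)
  out <- seq
  hit <- pos > 0L
  out[hit] <- substr(seq[hit], 1L, pos[hit] - 1L)
  out
}

#' Read-structure policy for the tag library
#'
#' @param barcode_len,umi_len Cell-barcode and UMI lengths on R1.
#' @param tag_offset 0-based start of the 15-bp tag on R2.
#' @param tag_len Tag length; fixed at 15.
#' @return A list of class `barcode_policy`.
#' @export
barcode_policy <- function(barcode_len = 16L, umi_len = 12L,
                           tag_offset = 0L, tag_len = 15L) {
  if (tag_len != 15L) stop("`tag_len` is fixed at 15")
  stopifnot(barcode_len >= 1L, umi_len >= 1L, tag_offset >= 0L)
  structure(list(barcode_len = as.integer(barcode_len),
                 umi_len = as.integer(umi_len),
                 tag_offset = as.integer(tag_offset),
                 tag_len = 15L),
            class = "barcode_policy")
}

# Core single-chunk demultiplexer: classifies reads and returns the
# distinct (barcode, umi, tag) triples plus the tally partition.
demux_chunk <- function(r1, r2, policy, tag_map, tags, cell_map, cell_whitelist) {
  n <- length(r1)
  need1 <- policy$barcode_len + policy$umi_len
  need2 <- policy$tag_offset + policy$tag_len
  skipped <- nchar(r1) < need1 | nchar(r2) < need2
  tally <- c(reads_seen = n, skipped = sum(skipped), unassigned = 0L,
             invalid = 0L, ambiguous = 0L, valid = 0L)
  keep <- !skipped
  if (!any(keep)) {
    return(list(triples = tibble::tibble(barcode = character(0),
                                         umi = character(0),
                                         tag = integer(0)),
                tally = tally))
  }
  bu <- extract_barcode_umi(r1[keep], policy)
  bc <- bu$barcode
  if (!is.null(cell_whitelist)) {
    idx <- h1_lookup(bc, cell_map)
    bc <- ifelse(is.na(idx) | idx == 0L, NA_character_,
                 cell_whitelist[pmax(idx, 1L)])
  }
  unassigned <- is.na(bc)
  tally["unassigned"] <- sum(unassigned)

  observed <- substr(r2[keep], policy$tag_offset + 1L, need2)
  tag_idx <- h1_lookup(observed, tag_map)
  consider <- !unassigned
  tally["invalid"] <- sum(consider & is.na(tag_idx))
  tally["ambiguous"] <- sum(consider & !is.na(tag_idx) & tag_idx == 0L)
  ok <- consider & !is.na(tag_idx) & tag_idx > 0L
  tally["valid"] <- sum(ok)
  list(
    triples = dplyr::distinct(tibble::tibble(
      barcode = bc[ok], umi = bu$umi[ok], tag = tag_idx[ok]
    )),
    tally = tally
  )
}

finish_demux <- function(triples, tally, tags, cell_whitelist) {
  triples <- dplyr::distinct(dplyr::bind_rows(triples))
  rows <- if (is.null(cell_whitelist)) sort(unique(triples$barcode)) else cell_whitelist
  counts <- dplyr::count(triples, .data$barcode, .data$tag, name = "count")
  mat <- Matrix::sparseMatrix(
    i = match(counts$barcode, rows), j = counts$tag, x = counts$count,
    dims = c(length(rows), length(tags)),
    dimnames = list(rows, names(tags) %||% paste0("tag", seq_along(tags)))
  )
  tally <- as.list(tally)
  tally$umi_counted <- sum(counts$count)
  structure(list(matrix = methods::as(mat, "CsparseMatrix"),
                 report = tally),
            class = "glyco_demux")
}

#' Demultiplex tag-library read pairs into a cell-by-tag UMI matrix
#'
#' For each read pair: extract barcode and UMI from R1, correct the
#' barcode against the cell whitelist when one is given, extract the
#' 15-bp tag at the policy's position on R2 (the poly-A tail lies after
#' the tag and is ignored), and match the tag at Hamming distance <= 1.
#' A cell's tag count increments once per distinct
#' (corrected barcode, UMI, tag) triple, so PCR duplicates collapse.
#'
#' @param reads Tibble with columns `r1` and `r2` (e.g. from
#'   [simulate_tag_reads()]), or see [demultiplex_fastq()] for files.
#' @param policy A [barcode_policy()].
#' @param tags Tag whitelist (character vector, optionally named).
#' @param cell_whitelist Optional known cell barcodes; when `NULL`, every
#'   observed barcode is kept verbatim (permissive mode, no correction).
#' @return A list of class `glyco_demux`: `matrix` (sparse cells x tags
#'   UMI counts; rows follow the whitelist when given, otherwise sorted
#'   observed barcodes) and `report`, a tally satisfying
#'   `reads_seen = valid + invalid + ambiguous + unassigned + skipped`.
#' @export
demultiplex <- function(reads, policy = barcode_policy(), tags,
                        cell_whitelist = NULL) {
  stopifnot(is.data.frame(reads), all(c("r1", "r2") %in% names(reads)))
  if (is.null(names(tags))) names(tags) <- paste0("tag", seq_along(tags))
  tag_map <- build_h1_map(unname(tags))
  cell_map <- if (!is.null(cell_whitelist)) build_h1_map(cell_whitelist)
  chunk <- demux_chunk(reads$r1, reads$r2, policy, tag_map, tags,
                       cell_map, cell_whitelist)
  finish_demux(list(chunk$triples), chunk$tally, tags, cell_whitelist)
}

#' Demultiplex paired FASTQ files in fixed-size chunks
#'
#' Streams the two FASTQ files (plain or gzip) `chunk_size` records at a
#' time, so files larger than memory can be processed; the per-chunk
#' classification matches [demultiplex()] exactly.
#'
#' @param r1_path,r2_path Paths to the paired FASTQ files.
#' @inheritParams demultiplex
#' @param chunk_size Records read per chunk.
#' @return Same as [demultiplex()].
#' @export
demultiplex_fastq <- function(r1_path, r2_path, policy = barcode_policy(),
                              tags, cell_whitelist = NULL,
                              chunk_size = 100000L) {
  if (is.null(names(tags))) names(tags) <- paste0("tag", seq_along(tags))
  tag_map <- build_h1_map(unname(tags))
  cell_map <- if (!is.null(cell_whitelist)) build_h1_map(cell_whitelist)
  triples <- list()
  tally <- c(reads_seen = 0L, skipped = 0L, unassigned = 0L,
             invalid = 0L, ambiguous = 0L, valid = 0L)
  skip <- 0L
  repeat {
    s1 <- read_fastq_chunk(r1_path, skip = skip, nrec = chunk_size)
    s2 <- read_fastq_chunk(r2_path, skip = skip, nrec = chunk_size)
    if (length(s1) != length(s2)) {
      stop("R1 and R2 FASTQ files have different record counts near record ",
           skip + min(length(s1), length(s2)) + 1L)
    }
    if (length(s1) == 0L) break
    chunk <- demux_chunk(s1, s2, policy, tag_map, tags, cell_map, cell_whitelist)
    triples[[length(triples) + 1L]] <- chunk$triples
    tally <- tally + chunk$tally
    skip <- skip + length(s1)
    if (length(s1) < chunk_size) break
  }
  finish_demux(triples, tally, tags, cell_whitelist)
}

#' @export
print.glyco_demux <- function(x, ...) {
  cat("<glyco_demux>", nrow(x$matrix), "cells x", ncol(x$matrix), "tags\n")
  r <- x$report
  cat(sprintf("  reads %d | valid %d | invalid %d | ambiguous %d | unassigned %d | skipped %d\n",
              r$reads_seen, r$valid, r$invalid, r$ambiguous, r$unassigned,
              r$skipped))
  cat("  UMIs counted:", r$umi_counted, "\n")
  invisible(x)
}
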