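# File-format plumbing: FASTQ via Biostrings, MatrixMarket via Matrix,
# tabular files via readr.

read_fastq_chunk <- function(path, skip = 0L, nrec = -1L) {
  res <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", skip = skip,
                                 nrec = nrec),
    error = function(e) {
      stop("malformed FASTQ in '", path, "' within records ", skip + 1L,
           "-", if (nrec > 0) skip + nrec else "end", ": ",
           conditionMessage(e), call. = FALSE)
    }
  )
  as.character(unname(res))
}

#' Write simulated tag reads as paired FASTQ files
#'
#' @param sim A `tag_sim` from [simulate_tag_reads()], or any tibble with
#'   columns `read_id`, `r1`, `r2`.
#' @param r1_path,r2_path Output paths; a `.gz` suffix triggers gzip.
#' @return Invisibly, the two paths.
#' @export
write_tag_fastq <- function(sim, r1_path, r2_path) {
  reads <- if (inherits(sim, "tag_sim")) sim$reads else sim
  stopifnot(all(c("read_id", "r1", "r2") %in% names(reads)))
  write_one <- function(seqs, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    q <- Biostrings::PhredQuality(strrep("I", Biostrings::width(x)))
    xq <- Biostrings::QualityScaledDNAStringSet(x, q)
    Biostrings::writeQualityScaledXStringSet(
      xq, path, compress = grepl("\\.gz$", path)
    )
  }
  write_one(reads$r1, reads$read_id, r1_path)
  write_one(reads$r2, reads$read_id, r2_path)
  invisible(c(r1_path, r2_path))
}

#' Write a sparse count matrix as MatrixMarket plus index TSVs
#'
#' @param mat Sparse cells x genes (or cells x tags) matrix with dimnames.
#' @param dir Output directory (created if needed).
#' @param prefix File prefix, e.g. `"total"` gives `total.mtx`.
#' @return Invisibly, the matrix path.
#' @export
write_count_matrix <- function(mat, dir, prefix) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mtx <- file.path(dir, paste0(prefix, ".mtx"))
  Matrix::writeMM(mat, mtx)
  readr::write_tsv(tibble::tibble(barcode = rownames(mat)),
                   file.path(dir, paste0(prefix, "_barcodes.tsv")),
                   col_names = FALSE)
  readr::write_tsv(tibble::tibble(feature = colnames(mat)),
                   file.path(dir, paste0(prefix, "_features.tsv")),
                   col_names = FALSE)
  invisible(mtx)
}

#' Read a sparse count matrix written by [write_count_matrix()]
#'
#' @param dir Directory holding the files.
#' @param prefix File prefix used at write time.
#' @return A sparse `dgCMatrix` with barcodes as rows, features as columns.
#' @export
read_count_matrix <- function(dir, prefix) {
  mat <- Matrix::readMM(file.path(dir, paste0(prefix, ".mtx")))
  bc <- readr::read_tsv(file.path(dir, paste0(prefix, "_barcodes.tsv")),
                        col_names = "barcode", show_col_types = FALSE)
  ft <- readr::read_tsv(file.path(dir, paste0(prefix, "_features.tsv")),
                        col_names = "feature", show_col_types = FALSE)
  dimnames(mat) <- list(bc$barcode, ft$feature)
  methods::as(mat, "CsparseMatrix")
}

#' Write / read the cell label table (barcode, sample, cluster, stage)
#' @param cells Tibble of per-cell labels.
#' @param path TSV path.
#' @return `read_labels()` returns the tibble; both return path/tibble
#'   invisibly/visibly as usual.
#' @export
write_labels <- function(cells, path) {
  readr::write_tsv(cells, path)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read a tag whitelist (one sequence per line, optional name column)
#' @param path Text file with one tag sequence per line, or two
#'   tab-separated columns `name`, `sequence`.
#' @return Named character vector of tag sequences.
#' @export
read_tag_whitelist <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (all(lengths(parts) >= 2L)) {
    stats::setNames(vapply(parts, `[[`, character(1), 2L),
                    vapply(parts, `[[`, character(1), 1L))
  } else {
    stats::setNames(trimws(lines), paste0("tag", seq_along(lines)))
  }
}
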