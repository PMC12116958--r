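# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so package functions are reproducible
#' under a caller-supplied seed without disturbing the session RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

DNA_BASES <- c("A", "C", "G", "T")

#' Random DNA sequences as a character vector
#' @noRd
random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Unique random DNA sequences (resamples on collision)
#' @noRd
random_dna_unique <- function(n, len) {
  out <- unique(random_dna(n, len))
  while (length(out) < n) {
    out <- unique(c(out, random_dna(n - length(out), len)))
  }
  out[seq_len(n)]
}

#' Split character sequences into a character matrix (one row per sequence)
#' @noRd
seq_char_matrix <- function(x, len = NULL) {
  if (length(x) == 0L) return(matrix(character(0), nrow = 0L))
  if (is.null(len)) len <- nchar(x[[1L]])
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = length(x), ncol = len, byrow = TRUE)
}

#' Substitute bases uniformly at random (never to the original base)
#'
#' Operates on a character matrix of sequences; each position flips with
#' probability `rate`. Guarantees every substitution changes the base, so a
#' per-base rate p gives Hamming-distance statistics with exact binomial form.
#' @noRd
substitute_bases <- function(mat, rate) {
  if (rate <= 0 || length(mat) == 0L) return(mat)
  hit <- which(stats::runif(length(mat)) < rate)
  if (length(hit) == 0L) return(mat)
  orig <- match(mat[hit], DNA_BASES)
  shift <- sample.int(3L, length(hit), replace = TRUE)
  mat[hit] <- DNA_BASES[(orig + shift - 1L) %% 4L + 1L]
  mat
}

#' Nearest-rank order statistic at probability q (rank = ceiling(q * n))
#' @noRd
nearest_rank <- function(x, q) {
  n <- length(x)
  sort(x)[max(1L, ceiling(q * n))]
}

first_true <- function(x) which(x)[1L]
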