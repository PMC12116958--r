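# Independent oracles used across tests. These deliberately use different
# algorithms from the package implementations they check.

# Exact two-sided Wilcoxon rank-sum p by bitmask enumeration of all
# subsets of the pooled sample (independent of the combn-based package
# path).
oracle_wilcoxon_p <- function(a, b) {
  na <- length(a)
  n <- na + length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(na)])
  sums <- c()
  for (mask in 0:(2^n - 1)) {
    bits <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    if (sum(bits) == na) sums <- c(sums, sum(r[bits]))
  }
  p_low <- mean(sums <= w_obs + 1e-9)
  p_high <- mean(sums >= w_obs - 1e-9)
  min(1, 2 * min(p_low, p_high))
}

# Brute-force tag matcher: scan the whole whitelist, no neighborhood hash.
oracle_match_tag <- function(observed, whitelist) {
  vapply(observed, function(o) {
    oc <- strsplit(o, "")[[1]]
    d <- vapply(whitelist, function(w) {
      wc <- strsplit(w, "")[[1]]
      sum(!(oc == wc & oc != "N" & wc != "N"))
    }, numeric(1))
    dmin <- min(d)
    if (dmin > 1) return(NA_integer_)
    if (sum(d == dmin) > 1) return(0L)
    which.min(d)
  }, integer(1), USE.NAMES = FALSE)
}

# Small deterministic tag whitelist at large pairwise distance.
toy_tags <- c(tagA = "AAAAAAAAAAAAAAA",
              tagB = "CCCCCCCCCCCCCCC",
              tagC = "GGGGGGGGGGGGGGG",
              tagD = "TTTTTTTTTTTTTTT")

# Mutate a sequence at the given 1-based positions to the given bases.
mutate_seq <- function(seq, pos, base) {
  ch <- strsplit(seq, "")[[1]]
  ch[pos] <- base
  paste(ch, collapse = "")
}
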