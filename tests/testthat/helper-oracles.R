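# Independent oracles used across the suite. These deliberately use different
# code paths from the implementation they check.

# Two-sided Fisher exact p for a 2x2 table by exhaustive hypergeometric
# enumeration: sum the probabilities of all tables with the observed margins
# whose probability does not exceed the observed table's.
fisher_p_oracle <- function(a, r1, b, r2) {
  m <- a + b        # total alt
  n <- r1 + r2      # total ref
  k <- a + r1       # group-1 total
  kk <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(kk, m, n, k)
  pa <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= pa * (1 + 1e-7)])
}

# Pooled two-sample t statistic from textbook formulas (var/mean), used as
# the exhaustive-split oracle for segmentation.
pooled_t_oracle <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp <- ((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) /
    (n1 + n2 - 2)
  abs(mean(x1) - mean(x2)) / sqrt(sp * (1 / n1 + 1 / n2))
}

best_split_oracle <- function(x, min_width = 5) {
  ks <- min_width:(length(x) - min_width)
  ts <- vapply(ks, function(k) {
    pooled_t_oracle(x[1:k], x[(k + 1):length(x)])
  }, numeric(1))
  ks[which.max(ts)]
}

# Exhaustive scan marking bases inside tandem runs of >= min_copies exact
# canonical hexamers (leftmost-greedy, mirroring maximal-run semantics).
brute_canonical_mask <- function(telo, min_copies = 2) {
  n <- nchar(telo)
  mask <- rep(FALSE, n)
  i <- 1
  while (i <= n - 5) {
    copies <- 0
    j <- i
    while (j + 5 <= n && substr(telo, j, j + 5) == "TTAGGG") {
      copies <- copies + 1
      j <- j + 6
    }
    if (copies >= min_copies) {
      mask[i:(j - 1)] <- TRUE
      i <- j
    } else {
      i <- i + 1
    }
  }
  mask
}

intervals_to_mask <- function(iv, len) {
  m <- rep(FALSE, len)
  for (i in seq_len(nrow(iv))) {
    if (iv$end[i] > iv$start[i]) m[(iv$start[i] + 1):iv$end[i]] <- TRUE
  }
  m
}
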