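# Independent brute-force oracles used across the suite.

# two-sided Fisher p by full hypergeometric enumeration with choose()
fisher_oracle <- function(meth_a, unmeth_a, meth_b, unmeth_b) {
  m <- meth_a + meth_b; u <- unmeth_a + unmeth_b
  k <- meth_a + unmeth_a; N <- m + u
  lo <- max(0, k - u); hi <- min(k, m)
  xs <- lo:hi
  prob <- choose(m, xs) * choose(u, k - xs) / choose(N, k)
  min(1, sum(prob[prob <= prob[xs == meth_a] * (1 + 1e-7)]))
}

# hand application of the BH step-up formula
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- pmin(rev(cummin(rev(q))), 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# per-base bitmap union length for intervals on one small genome
bitmap_bp <- function(df, genome) {
  total <- 0
  for (i in seq_len(nrow(genome))) {
    bits <- logical(genome$length[i])
    rows <- df[df$chrom == genome$chrom[i], , drop = FALSE]
    for (j in seq_len(nrow(rows)))
      bits[(rows$start[j] + 1):rows$end[j]] <- TRUE
    total <- total + sum(bits)
  }
  total
}

# exact hypergeometric upper tail by combinatorial summation
hyper_tail_oracle <- function(x, m, N, k) {
  xs <- x:min(k, m)
  sum(choose(m, xs) * choose(N - m, k - xs)) / choose(N, k)
}

# quadratic all-pairs overlap (>= 1 bp, half-open)
overlap_pairs_oracle <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & b$end > a$start[i])
  }, logical(1))
}

random_interval_df <- function(n, genome, max_len = 500) {
  ci <- sample.int(nrow(genome), n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  start <- floor(runif(n) * (genome$length[ci] - len))
  data.frame(chrom = genome$chrom[ci], start = start, end = start + len,
             stringsAsFactors = FALSE)
}
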