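# Independent brute-force oracles the implementation is checked against.

# Exact two-sided Mann-Whitney p-value by enumerating every assignment of
# the pooled observations to the two group sizes (tie-free data only).
mwu_exact_oracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(length(pooled), n)
  u_all <- apply(combos, 2L, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(p, 1)
}

# Benjamini-Hochberg step-up by the textbook formula:
# adj_(i) = min_{j >= i} p_(j) * m / j, clipped at 1, in input order.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    vals <- sorted[i:m] * m / (i:m)
    adj_sorted[i] <- min(1, min(vals))
  }
  adj <- numeric(m)
  adj[ord] <- adj_sorted
  adj
}
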