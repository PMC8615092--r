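# Independent brute-force oracles. These deliberately re-derive each
# statistic from its definition (explicit per-step sums, no shared code
# with the package internals).

# ssGSEA by direct ECDF evaluation: for every prefix of the
# decreasing-rank gene walk, recompute both cumulative distribution
# values from scratch.
ssgsea_brute <- function(tpm, set, alpha = 0.25) {
  N <- length(tpm)
  r <- rank(tpm, ties.method = "average")
  walk <- order(r, decreasing = TRUE)
  inset <- names(tpm)[walk] %in% set
  n_in <- sum(inset)
  if (n_in == 0 || n_in == N) return(NA_real_)
  denom_in <- sum(r[names(tpm) %in% set]^alpha)
  es <- 0
  for (i in seq_len(N)) {
    p_in <- sum((r[walk][seq_len(i)]^alpha)[inset[seq_len(i)]]) / denom_in
    p_out <- sum(!inset[seq_len(i)]) / (N - n_in)
    es <- es + p_in - p_out
  }
  es
}

# Spearman as Pearson on midranks, computed from first principles.
spearman_brute <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  rx <- rank(x[ok], ties.method = "average")
  ry <- rank(y[ok], ties.method = "average")
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}
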