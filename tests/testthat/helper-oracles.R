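# Independent oracles, deliberately written along different code paths than
# the package implementations they check.

# U statistic by explicit pairwise counting (no ranks).
oracle_u_pairwise <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

# Exact two-tailed Mann-Whitney p by bitmask enumeration of all relabelings.
oracle_mw_two_tailed <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); n1 <- length(a)
  u_obs <- min(oracle_u_pairwise(a, b), oracle_u_pairwise(b, a))
  hits <- 0L; total <- 0L
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(idx) != n1) next
    total <- total + 1L
    u <- oracle_u_pairwise(pooled[idx], pooled[-idx])
    if (u <= u_obs + 1e-9) hits <- hits + 1L
  }
  min(1, 2 * hits / total)
}

# Hypergeometric upper tail by exhaustive draw enumeration: universe of N
# genes of which the first K are annotated; counts draws with >= k overlap.
oracle_hypergeom_tail <- function(k, n, K, N) {
  if (n == 0) return(as.numeric(k == 0))
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= K)
  mean(overlap >= k)
}

# Per-row brute-force replicate filter: detection count over given columns.
oracle_detect_count <- function(mat, cols, min_psm) {
  vapply(seq_len(nrow(mat)), function(i) {
    sum(vapply(cols, function(cl) mat[i, cl] >= min_psm, logical(1)))
  }, integer(1))
}
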