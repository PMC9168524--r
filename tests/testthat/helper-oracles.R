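# Independent brute-force oracles for the statistical primitives.
# These deliberately avoid rank()/the package internals: midranks are
# built from explicit pairwise comparisons and the Mann-Whitney U from
# pairwise wins, so agreement with the package is a genuine
# cross-check.

oracle_midrank <- function(x) {
  vapply(x, function(v) sum(x < v) + (1 + sum(x == v)) / 2, numeric(1))
}

oracle_spearman_rho <- function(x, y) {
  rx <- oracle_midrank(x)
  ry <- oracle_midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# U for group a by pairwise wins (ties count 1/2)
oracle_u <- function(a, b) {
  sum(vapply(a, function(ai) sum(ai > b) + 0.5 * sum(ai == b),
             numeric(1)))
}

# exact two-sided Mann-Whitney p by enumerating all C(n1+n2, n1)
# labelings of the pooled values
oracle_mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  sets <- utils::combn(length(pooled), n1)
  u_all <- apply(sets, 2, function(idx)
    oracle_u(pooled[idx], pooled[-idx]))
  u_obs <- oracle_u(a, b)
  lo <- min(u_obs, n1 * length(b) - u_obs)
  hi <- n1 * length(b) - lo
  mean(u_all <= lo + 1e-9 | u_all >= hi - 1e-9)
}

# all permutations of seq_len(n), rows
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(pos)
    t(apply(sub, 1L, append, values = n, after = pos - 1L))))
}
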