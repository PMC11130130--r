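# a small, fast truth for structural tests
small_truth <- function(seed = 1, ...) {
  truth_spec(n_zones = 4, fields_per_zone = 150, seed = seed, ...)
}

# all permutations of 1..n (used as an enumeration oracle for small n)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)
    # insert n at position pos
    if (pos < n) block <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
                                sub[, pos:(n - 1L), drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

# independent squared standardized correlation statistic (oracle form)
oracle_stat <- function(g, y) (length(y) - 1) * stats::cor(g, y)^2
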