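# Shared helpers: independent oracles and small generators.

# Brute-force rank oracle: rank of each sample by explicit pairwise
# comparison, ties to the earlier index. Independent of rank() and of the
# package's vectorized encoding.
brute_force_pattern <- function(w) {
  m <- length(w)
  r <- integer(m)
  for (j in seq_len(m)) {
    smaller <- 0L
    for (i in seq_len(m)) {
      if (i == j) next
      if (w[i] < w[j] || (w[i] == w[j] && i < j)) smaller <- smaller + 1L
    }
    r[j] <- smaller + 1L
  }
  r
}

# All permutations of 1:m, one per row (recursive enumeration).
all_permutations <- function(m) {
  if (m == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(m - 1L)
  out <- matrix(0L, nrow(sub) * m, m)
  row <- 0L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(m)) {
      row <- row + 1L
      out[row, ] <- append(sub[i, ], m, after = pos - 1L)
    }
  }
  out
}

# Plug-in Shannon entropy of a count vector (oracle for the memoryless
# variance check), zero counts excluded.
plugin_entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

# AR(1) series, handy as a generic correlated test signal.
ar1_series <- function(n, phi = 0.8, seed = 1) {
  set.seed(seed)
  as.numeric(stats::filter(rnorm(n), phi, method = "recursive"))
}

make_quiet_ensemble <- function(...) {
  suppressWarnings(make_ensemble(...))
}
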