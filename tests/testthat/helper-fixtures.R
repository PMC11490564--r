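# Shared fixtures, all generated in code.

# random composition vector with at least 2 positive entries
rand_comp <- function(n_asv, max_count = 50) {
  repeat {
    x <- rpois(n_asv, lambda = runif(1, 0.5, 8))
    if (sum(x > 0) >= 2) return(x)
  }
}

# toy dataset written to disk once per test run
toy_paths <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "gransucc-toy")
      write_synthetic_dataset(toy_fixture(), dir)
    }
    list(table = file.path(dir, "prok_counts.tsv"),
         tree = file.path(dir, "prok_tree.nwk"),
         env = file.path(dir, "env.csv"),
         euk_table = file.path(dir, "euk_counts.tsv"),
         euk_tree = file.path(dir, "euk_tree.nwk"))
  }
})

# exact null moments of a community statistic under full label permutation
# (brute force over all n! permutations; only for tiny pools)
exhaustive_null_moments <- function(stat_fun, n_pool) {
  perms <- gtools_permutations(n_pool)
  vals <- apply(perms, 1, stat_fun)
  list(mean = mean(vals), sd = sd(vals) * sqrt((length(vals) - 1) /
                                                 length(vals)))
}

# all permutations of 1..n as a matrix (one per row), no dependencies
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1
  for (k in seq_len(n)) {
    for (r in seq_len(nrow(sub))) {
      rest <- seq_len(n)[-k]
      out[row, ] <- c(k, rest[sub[r, ]])
      row <- row + 1
    }
  }
  out
}
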