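# Independent oracles used by the tests. These deliberately take the
# slowest, most transparent route so they stay independent of the package's
# implementation paths.

# Hamming distance between two equal-length strings, character by character.
slow_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Connected components of the <= max_mismatch graph by transitive closure
# over an explicit adjacency matrix (no union-find).
brute_components <- function(seqs, max_mismatch) {
  n <- length(seqs)
  adj <- diag(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (slow_hamming(seqs[i], seqs[j]) <= max_mismatch) adj[i, j] <- TRUE
    }
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj > 0)) break
    adj <- nxt
  }
  comp <- integer(n)
  next_id <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      next_id <- next_id + 1L
      comp[adj[i, ]] <- next_id
    }
  }
  comp
}

# Upper-tail hypergeometric probability by summing the pmf written directly
# from binomial coefficients (no log-space).
enum_hyper_sf <- function(k, N, K, n) {
  hi <- min(K, n)
  pmf <- choose(K, 0:hi) * choose(N - K, n - (0:hi)) / choose(N, n)
  if (k <= 0) return(1)
  if (k > hi) return(0)
  sum(pmf[(k + 1):(hi + 1)])
}

# Exhaustive-draw oracle for tiny cases: enumerate every size-n subset of a
# population with K marked items and count subsets with >= k marked.
draw_enum_sf <- function(k, N, K, n) {
  draws <- utils::combn(N, n)
  marked <- colSums(draws <= K)
  sum(marked >= k) / ncol(draws)
}
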