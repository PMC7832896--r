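# Internal helpers shared across the pipeline stages.

DNA_BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
#' Run `expr` under a private RNG stream seeded with `seed`, restoring the
#' caller's RNG state afterwards so library code never perturbs user scripts.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(expr)
}

#' @noRd
#' Pack equal-length DNA strings into an integer matrix (one column per
#' sequence, one row per position) for fast vectorised Hamming arithmetic.
seq_matrix <- function(seqs) {
  if (length(seqs) == 0L) {
    return(matrix(integer(0), nrow = 0L, ncol = 0L))
  }
  len <- unique(nchar(seqs))
  if (length(len) != 1L) {
    stop("sequences must have uniform length, found lengths: ",
         paste(sort(len), collapse = ", "))
  }
  matrix(as.integer(charToRaw(paste(seqs, collapse = ""))),
         nrow = len, ncol = length(seqs))
}

#' @noRd
#' Hamming distance from one sequence to each column of a packed matrix.
hamming_to <- function(mat, seq) {
  if (ncol(mat) == 0L) return(integer(0))
  v <- as.integer(charToRaw(seq))
  if (length(v) != nrow(mat)) {
    stop("sequence length ", length(v), " does not match matrix rows ",
         nrow(mat))
  }
  colSums(mat != v)
}

#' @noRd
#' Pairwise Hamming distances between equal-length strings (dense matrix).
hamming_matrix <- function(seqs) {
  n <- length(seqs)
  d <- matrix(0L, n, n)
  if (n < 2L) return(d)
  m <- seq_matrix(seqs)
  for (i in seq_len(n - 1L)) {
    rest <- (i + 1L):n
    di <- colSums(m[, rest, drop = FALSE] != m[, i])
    d[i, rest] <- di
    d[rest, i] <- di
  }
  d
}

#' @noRd
#' Substitute `k` positions of `seq` (1-based, within [from, to]) with a
#' different base each. Used for gametolog divergence and planted variants.
mutate_positions <- function(seq, k, from, to) {
  if (k <= 0L) return(seq)
  chars <- strsplit(seq, "")[[1L]]
  pos <- sample(from:to, k)
  for (p in pos) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' @noRd
#' Phred scores (offset 33) for equal-length quality strings, as an
#' L x n integer matrix.
phred_matrix <- function(quals) {
  if (length(quals) == 0L) {
    return(matrix(integer(0), nrow = 0L, ncol = 0L))
  }
  len <- unique(nchar(quals))
  if (length(len) != 1L) {
    stop("quality strings must have uniform length")
  }
  matrix(as.integer(charToRaw(paste(quals, collapse = ""))) - 33L,
         nrow = len, ncol = length(quals))
}

#' @noRd
stamp_header <- function(con, params) {
  for (nm in names(params)) {
    writeLines(sprintf("# %s=%s", nm, paste(params[[nm]], collapse = ",")),
               con)
  }
}
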