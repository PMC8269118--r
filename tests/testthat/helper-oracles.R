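# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive re-implementations (loops, recursion, enumeration) kept
# separate from the package's own code paths.

# Cell-by-cell standardized-residual weight matrix (loops, no vectorization)
eq3_oracle <- function(m1) {
  m1 <- unclass(m1)
  N <- sum(m1)
  x <- numeric(nrow(m1)); y <- numeric(ncol(m1))
  for (i in seq_len(nrow(m1))) for (j in seq_len(ncol(m1))) {
    x[i] <- x[i] + m1[i, j]; y[j] <- y[j] + m1[i, j]
  }
  w <- matrix(0, nrow(m1), ncol(m1))
  for (i in seq_len(nrow(m1))) for (j in seq_len(ncol(m1))) {
    p <- x[i] * y[j] / N^2
    if (p > 0 && p < 1) w[i, j] <- (m1[i, j] - N * p) / sqrt(N * p * (1 - p))
  }
  w
}

# Scoring rule shared by the enumeration oracle: diagonal move consuming
# (seq i, probe j) scores mt[probe[j], seq[i-1] + 5*(seq[i]-1)] for i >= 2
# and 0 at i = 1; gaps cost del.
oracle_w <- function(mt, probe, seq) {
  L <- length(seq)
  w <- matrix(0, L, L)
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (i >= 2) w[i, j] <- mt[probe[j], seq[i - 1] + 5 * (seq[i] - 1)]
  }
  w
}

# Exhaustive enumeration of all monotone local paths (feasible for L <= ~6):
# maximum total score over every path made of match / gap moves, starting at
# any match column. The empty alignment scores 0.
enum_local_align_score <- function(mt, probe, seq, del) {
  L <- length(seq)
  w <- oracle_w(mt, probe, seq)
  best <- 0
  recurse <- function(i, j, score) {
    if (score > best) best <<- score
    if (i < L && j < L) recurse(i + 1, j + 1, score + w[i + 1, j + 1])
    if (j < L) recurse(i, j + 1, score - del)
    if (i < L) recurse(i + 1, j, score - del)
  }
  for (i in seq_len(L)) for (j in seq_len(L)) recurse(i, j, w[i, j])
  best
}

# Plain-R mirror of the local-alignment recurrence (independent coding of
# the same mathematical definition; no shared code with the C++ engine)
r_local_align_score <- function(mt, probe, seq, del) {
  L <- length(seq)
  F <- matrix(0, L + 1, L + 1)
  best <- 0
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      sub <- if (i >= 2) mt[probe[j], seq[i - 1] + 5 * (seq[i] - 1)] else 0
      v <- max(0,
               F[i, j] + sub,
               F[i + 1, j] - del,
               F[i, j + 1] - del)
      F[i + 1, j + 1] <- v
      if (v > best) best <- v
    }
  }
  best
}

# Brute-force minimum Euclidean distance over explicit row rotations
rotation_distance_oracle <- function(a, b) {
  n <- nrow(a)
  vals <- numeric(n)
  for (s in 0:(n - 1)) {
    rot <- a[((seq_len(n) - 1 + s) %% n) + 1, , drop = FALSE]
    vals[s + 1] <- sqrt(sum((rot - b)^2))
  }
  min(vals)
}

# Manual recount of the divergence degree from a character matrix
# (rows = repeat copies, NA = gap), mirroring the published procedure
divergence_recount_oracle <- function(mat, alphabet) {
  k <- nrow(mat)
  keep <- which(colSums(!is.na(mat)) >= k / 2)
  v <- 0; v1 <- 0
  for (j in keep) {
    col <- mat[, j]
    counts <- integer(length(alphabet))
    for (a in seq_along(alphabet)) counts[a] <- sum(col == alphabet[a], na.rm = TRUE)
    v <- v + max(counts)
    v1 <- v1 + sum(counts)
  }
  1 - v / v1
}

# A weight matrix rewarding exactly the adjacent-pair categories of a clean
# tandem of `unit` (period n), +hi on pattern pairs, -lo elsewhere
pattern_matrix <- function(unit, hi = 10, lo = -10) {
  n <- length(unit)
  mt <- matrix(lo, n, 25)
  for (pos in seq_len(n)) {
    prev <- unit[((pos - 2) %% n) + 1]
    cur <- unit[pos]
    mt[pos, prev + 5 * (cur - 1)] <- hi
  }
  structure(mt, class = c("norm_weight_matrix", "matrix", "array"))
}

# Random normalized matrix via the package's own generation path
random_norm_matrix <- function(n, seed) {
  generate_matrix_set(n, count = 1L, seed = seed, probe_copies = 100L)[[1L]]
}
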