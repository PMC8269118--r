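#' Cyclically rotate the rows of a matrix
#'
#' Rotation by \code{shift} moves row i+shift into row i (rows wrap around),
#' i.e. advances the repeat phase by \code{shift} positions.
#'
#' @param m Matrix.
#' @param shift Integer rotation (any value; taken mod nrow).
#' @return Rotated matrix.
#' @export
rotate_rows <- function(m, shift) {
  n <- nrow(m)
  s <- ((shift %% n) + n) %% n
  out <- unclass(m)[((seq_len(n) - 1L + s) %% n) + 1L, , drop = FALSE]
  rownames(out) <- rownames(m)
  out
}

#' Cyclic Euclidean distance between two repeat weight matrices
#'
#' Repeat matrices of the same consensus length are compared as points in
#' n x 25 space, but their phase is arbitrary: the Euclidean distance
#' \deqn{B = \sqrt{\sum_i \sum_j (m_1(i,j) - m_2(i,j))^2}}
#' is evaluated for all n cyclic row rotations of the second matrix and the
#' minimum B_min is taken. \code{best_shift} is the rotation s such that
#' \code{b} matches \code{rotate_rows(a, s)} most closely (so
#' \code{cyclic_matrix_distance(a, rotate_rows(a, s))$best_shift == s}).
#'
#' @param a,b Numeric matrices with the same dimensions (n x 25).
#' @return Object of class \code{cyclic_distance}: \code{B_min},
#'   \code{best_shift} (in 0..n-1), \code{all} (distance per shift).
#' @export
cyclic_matrix_distance <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  if (!all(dim(a) == dim(b)))
    stop_invalid("matrices have different dimensions")
  n <- nrow(a)
  d <- vapply(0:(n - 1L), function(s) {
    sqrt(sum((rotate_rows(a, s) - b)^2))
  }, numeric(1))
  best <- which.min(d)  # ties: smallest shift
  structure(list(B_min = d[best], best_shift = best - 1L, all = d),
            class = "cyclic_distance")
}

#' Pairwise cyclic distance matrix
#'
#' @param matrices List of n x 25 matrices sharing the same n.
#' @return A symmetric matrix of B_min values.
#' @export
cyclic_distance_matrix <- function(matrices) {
  m <- length(matrices)
  if (m < 2L) stop_invalid("need at least 2 matrices")
  n <- nrow(matrices[[1L]])
  if (!all(vapply(matrices, nrow, integer(1)) == n))
    stop_invalid("all matrices must share the same number of rows")
  d <- matrix(0, m, m)
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      d[i, j] <- d[j, i] <- cyclic_matrix_distance(matrices[[i]],
                                                   matrices[[j]])$B_min
    }
  }
  d
}

#' Complete-linkage clustering of repeat weight matrices
#'
#' Agglomerates the matrices on their pairwise cyclic distances with
#' complete linkage and cuts the dendrogram at height \code{cut}.
#'
#' @param matrices List of n x 25 matrices (same n), or a precomputed
#'   symmetric distance matrix via \code{dist_matrix}.
#' @param cut Cut level B0.
#' @param dist_matrix Optional precomputed pairwise distance matrix.
#' @return Object of class \code{class_partition}: \code{hclust} (merge
#'   tree), \code{cut}, \code{membership} (integer vector), \code{classes}
#'   (list of member index vectors).
#' @export
cluster_matrices <- function(matrices, cut, dist_matrix = NULL) {
  d <- dist_matrix %||% cyclic_distance_matrix(matrices)
  hc <- stats::hclust(stats::as.dist(d), method = "complete")
  membership <- stats::cutree(hc, h = cut)
  classes <- split(seq_along(membership), membership)
  names(classes) <- NULL
  structure(list(hclust = hc, cut = cut, membership = membership,
                 classes = classes),
            class = "class_partition")
}

#' @export
print.class_partition <- function(x, ...) {
  sizes <- lengths(x$classes)
  cat(sprintf("<class_partition> %d members, %d classes at B0 = %g (sizes: %s)\n",
              length(x$membership), length(x$classes), x$cut,
              paste(sort(sizes, decreasing = TRUE), collapse = ", ")))
  invisible(x)
}

#' Randomly rearrange the elements of a matrix
#'
#' Draws a uniform random permutation of all n x 25 cells; the multiset of
#' values (and hence the sum of squares R^2) is preserved. Used to build the
#' randomized twin set against which the clustering cut is calibrated.
#'
#' @param m Matrix.
#' @param seed Integer seed.
#' @return Matrix of the same dimensions.
#' @export
shuffle_matrix_elements <- function(m, seed = 1L) {
  set.seed(seed)
  out <- matrix(sample(as.vector(unclass(m))), nrow(m), ncol(m))
  dimnames(out) <- dimnames(m)
  out
}

#' Significance of a clustering cut against randomized matrices
#'
#' Builds a randomized twin of the input set (each matrix's elements
#' shuffled), clusters both sets at every level of a grid of cut heights B,
#' and compares the mean class sizes:
#' \deqn{Z_n(B) = \frac{X_n(B) - Y_n(B)}
#'   {\sqrt{D(X_n(B))/r_1 + D(Y_n(B))/r_2}}}
#' where X/Y are the mean class sizes of the real and randomized sets,
#' D(.) the population variances of class sizes across classes, and r1/r2
#' the class counts at that level. The recommended cut B0 is the smallest
#' grid level with Z_n(B) > 10.
#'
#' @param real List of at least 10 n x 25 matrices (same n).
#' @param seed Integer seed for the element shuffles.
#' @param B_grid Cut levels; default 40 levels spanning the 1st-99th
#'   percentile of the real pairwise distances.
#' @return Object of class \code{cut_significance}: \code{B_grid}, \code{X},
#'   \code{Y}, \code{DX}, \code{DY}, \code{r1}, \code{r2}, \code{Z},
#'   \code{B0} (NA if no level exceeds 10).
#' @export
cut_significance <- function(real, seed = 1L, B_grid = NULL) {
  if (length(real) < 10L) stop_invalid("need at least 10 matrices")
  rand <- lapply(seq_along(real), function(i)
    shuffle_matrix_elements(real[[i]], seed = substream_seed(seed, i, 13L)))
  d_real <- cyclic_distance_matrix(real)
  d_rand <- cyclic_distance_matrix(rand)
  if (is.null(B_grid)) {
    qs <- stats::quantile(d_real[upper.tri(d_real)], c(0.01, 0.99))
    if (diff(qs) <= 0) stop_invalid("degenerate distance grid")
    B_grid <- seq(qs[[1L]], qs[[2L]], length.out = 40L)
  }
  if (length(B_grid) < 2L) stop_invalid("degenerate grid: need >= 2 levels")
  hc_real <- stats::hclust(stats::as.dist(d_real), method = "complete")
  hc_rand <- stats::hclust(stats::as.dist(d_rand), method = "complete")
  pop_var <- function(x) mean((x - mean(x))^2)
  stat <- function(hc, B) {
    sizes <- tabulate(stats::cutree(hc, h = B))
    c(mean = mean(sizes), var = pop_var(sizes), r = length(sizes))
  }
  X <- Y <- DX <- DY <- Z <- numeric(length(B_grid))
  r1 <- r2 <- integer(length(B_grid))
  for (g in seq_along(B_grid)) {
    sr <- stat(hc_real, B_grid[g]); sq <- stat(hc_rand, B_grid[g])
    X[g] <- sr[["mean"]]; DX[g] <- sr[["var"]]; r1[g] <- sr[["r"]]
    Y[g] <- sq[["mean"]]; DY[g] <- sq[["var"]]; r2[g] <- sq[["r"]]
    se <- sqrt(DX[g] / r1[g] + DY[g] / r2[g])
    # zero variance on both sides: identical means are unremarkable (Z = 0),
    # different means separate perfectly (limit Z = +/-Inf)
    Z[g] <- if (se > 0) (X[g] - Y[g]) / se
            else if (X[g] == Y[g]) 0 else sign(X[g] - Y[g]) * Inf
  }
  b0 <- B_grid[which(Z > 10)[1L]]
  structure(list(B_grid = B_grid, X = X, Y = Y, DX = DX, DY = DY,
                 r1 = r1, r2 = r2, Z = Z,
                 B0 = if (length(b0)) b0 else NA_real_),
            class = "cut_significance")
}

#' Phase-aligned consensus matrix of a class
#'
#' The central member is the one minimizing the summed cyclic distance to
#' the rest of the class (ties to the smallest index); every other member is
#' rotated to the phase minimizing its distance to the central matrix, and
#' the cell-wise mean of the aligned members is returned.
#'
#' @param members List of n x 25 matrices forming one class.
#' @return Object of class \code{class_matrix}: \code{central} (index into
#'   \code{members}), \code{matrix} (n x 25 consensus).
#' @export
class_consensus_matrix <- function(members) {
  if (!length(members)) stop_invalid("empty class")
  if (length(members) == 1L)
    return(structure(list(central = 1L, matrix = unclass(members[[1L]])),
                     class = "class_matrix"))
  m <- length(members)
  d <- cyclic_distance_matrix(members)
  central <- which.min(rowSums(d))  # ties: smallest index
  ctr <- unclass(members[[central]])
  acc <- ctr
  for (i in seq_len(m)) {
    if (i == central) next
    cd <- cyclic_matrix_distance(members[[i]], ctr)
    # rotate member i so that it sits in the central matrix's phase
    acc <- acc + rotate_rows(members[[i]], cd$best_shift)
  }
  structure(list(central = central, matrix = acc / m),
            class = "class_matrix")
}

#' Export a clustering dendrogram in Newick format
#'
#' @param partition A \code{class_partition}.
#' @param path Output file.
#' @param labels Optional tip labels.
#' @return The path, invisibly.
#' @export
export_dendrogram_newick <- function(partition, path, labels = NULL) {
  hc <- partition$hclust
  if (!is.null(labels)) hc$labels <- labels
  if (is.null(hc$labels)) hc$labels <- paste0("m", seq_along(partition$membership))
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
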