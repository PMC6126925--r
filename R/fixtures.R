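#' Synthetic fixtures with known structure
#'
#' Generators for controlled test inputs: `random_reciprocal_matrix()`
#' draws a valid interaction matrix with uniform pairwise survival
#' probabilities; `random_tournament()` a dominance network with one
#' random direction and weight per pair; `planted_cluster_traits()` a
#' point cloud with `k` well-separated clusters of known spread in trait
#' space; `planted_cycle_network()` a single directed cycle with
#' prescribed edge weights.
#'
#' @param n number of strains / nodes.
#' @return `random_reciprocal_matrix()`: an [interaction_matrix()].
#' @export
random_reciprocal_matrix <- function(n) {
  stopifnot(n >= 1)
  m <- matrix(0.5, n, n)
  if (n >= 2) {
    up <- upper.tri(m)
    m[up] <- stats::runif(sum(up))
    m[lower.tri(m)] <- 1 - t(m)[lower.tri(m)]
  }
  interaction_matrix(m)
}

#' @rdname random_reciprocal_matrix
#' @return `random_tournament()`: a `dominance_network` matrix in which
#'   every pair has exactly one directed edge with weight drawn uniformly
#'   from (0, 1).
#' @export
random_tournament <- function(n) {
  stopifnot(n >= 1)
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    w <- stats::runif(1)
    if (stats::runif(1) < 0.5) W[i, j] <- w else W[j, i] <- w
  }
  structure(W, class = c("dominance_network", "matrix"))
}

#' @rdname random_reciprocal_matrix
#' @param k number of planted clusters.
#' @param spread within-cluster standard deviation per coordinate.
#' @param separation pairwise Euclidean distance between cluster centres.
#' @param n_per points per cluster.
#' @param dim ambient dimension (at least `k`).
#' @return `planted_cluster_traits()`: a numeric matrix of coordinates
#'   with the true cluster assignment in `attr(, "cluster")`.
#' @export
planted_cluster_traits <- function(k, spread, separation, n_per = 5,
                                   dim = max(4, k)) {
  stopifnot(k >= 1, dim >= k)
  centers <- matrix(0, k, dim)
  for (i in seq_len(k)) centers[i, i] <- separation / sqrt(2)
  idx <- rep(seq_len(k), each = n_per)
  pts <- centers[idx, , drop = FALSE] +
    matrix(stats::rnorm(length(idx) * dim, 0, spread), ncol = dim)
  attr(pts, "cluster") <- idx
  pts
}

#' @rdname random_reciprocal_matrix
#' @param weights edge weights around the cycle (node `i` beats node
#'   `i + 1`, the last beats the first).
#' @return `planted_cycle_network()`: a `dominance_network` matrix whose
#'   only cycle is the planted one, with strength `min(weights)`.
#' @export
planted_cycle_network <- function(weights) {
  n <- length(weights)
  stopifnot(n >= 3, all(weights > 0), all(weights <= 1))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) W[i, i %% n + 1] <- weights[i]
  structure(W, class = c("dominance_network", "matrix"))
}
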