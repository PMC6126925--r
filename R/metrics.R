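#' Distances between interaction traits
#'
#' Euclidean distance between the rows of the interaction matrix, excluding
#' for each pair \eqn{(\alpha,\beta)} the two coordinates \eqn{\alpha} and
#' \eqn{\beta} themselves.  Raw rows of any two strains differ trivially at
#' their mutual coordinates (\eqn{I_{\alpha\beta}} vs
#' \eqn{I_{\beta\alpha} = 1 - I_{\alpha\beta}}), which would inflate every
#' distance; dropping the self- and mutual entries makes the distance a
#' symmetric measure of how the two strains behave towards the rest of the
#' community.  For communities of two strains (no third parties) the
#' convention \eqn{d = |I_{\alpha\beta} - I_{\beta\alpha}|/\sqrt{2}} is
#' used.
#'
#' @param im an [interaction_matrix()], or a plain reciprocal matrix.
#' @return A symmetric distance matrix with zero diagonal, labelled by
#'   strain handle.
#' @export
trait_distances <- function(im) {
  m <- if (inherits(im, "interaction_matrix")) im$entries else im
  n <- nrow(m)
  if (is.null(n) || n == 0) stop("empty interaction matrix")
  if (n == 1) return(matrix(0, 1, 1, dimnames = dimnames(m)))
  if (n == 2) {
    d <- abs(m[1, 2] - m[2, 1]) / sqrt(2)
    D <- matrix(c(0, d, d, 0), 2, 2, dimnames = dimnames(m))
    return(D)
  }
  D2full <- as.matrix(stats::dist(m))^2
  # both excluded coordinates contribute (I_ab - 0.5)^2 each:
  # (I_aa - I_ba)^2 = (0.5 - (1 - I_ab))^2 = (I_ab - 0.5)^2, likewise for b
  D2 <- D2full - 2 * (m - 0.5)^2
  D2[D2 < 0] <- 0
  diag(D2) <- 0
  sqrt(D2)
}

#' Minimum spanning tree in trait space
#'
#' `minimum_spanning_tree()` returns the MST edge list of a distance
#' matrix; `smst()` its total edge weight (the *size of the minimum
#' spanning tree*), used as a functional-diversity measure: it grows as the
#' community spreads out in interaction trait space and is insensitive to
#' duplicated strains.
#'
#' @param D symmetric distance matrix (e.g. from [trait_distances()]).
#' @return For `minimum_spanning_tree()`, a data frame with columns `from`,
#'   `to` (indices into `D`) and `weight`, with \eqn{n - 1} rows; for
#'   `smst()`, a single non-negative number (0 for fewer than two points).
#' @export
minimum_spanning_tree <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n <= 1) return(data.frame(from = integer(), to = integer(),
                                weight = numeric()))
  # complete graph: every pair is an edge, zero distances included
  g <- igraph::add_edges(
    igraph::make_empty_graph(n, directed = FALSE),
    t(which(upper.tri(D), arr.ind = TRUE)))
  igraph::E(g)$weight <- D[upper.tri(D)]
  mt <- igraph::mst(g, weights = igraph::E(g)$weight)
  el <- igraph::as_edgelist(mt, names = FALSE)
  data.frame(from = as.integer(el[, 1]), to = as.integer(el[, 2]),
             weight = igraph::E(mt)$weight)
}

#' @rdname minimum_spanning_tree
#' @export
smst <- function(D) {
  sum(minimum_spanning_tree(D)$weight)
}

#' Branch-length threshold separating species from strains
#'
#' The MST branch-length distribution of a structured community is
#' two-level: short within-cluster edges and a clearly separated set of
#' long between-cluster edges.  The automatic threshold is placed in the
#' largest relative gap of the sorted branch lengths (geometric midpoint),
#' provided that gap exceeds `min_ratio`; otherwise the community is
#' treated as a single cluster (`Inf`).
#'
#' @param mst_edges edge list from [minimum_spanning_tree()].
#' @param min_ratio smallest length ratio between consecutive sorted branch
#'   lengths that counts as a cluster gap.
#' @return A threshold length (possibly `Inf`).
#' @export
species_threshold <- function(mst_edges, min_ratio = 3) {
  l <- sort(mst_edges$weight)
  if (length(l) < 2) return(Inf)
  eps <- 1e-12
  ratio <- (l[-1] + eps) / (l[-length(l)] + eps)
  i <- which.max(ratio)
  if (ratio[i] < min_ratio) return(Inf)
  sqrt((l[i] + eps) * (l[i + 1] + eps))
}

#' Cluster strains into species in trait space
#'
#' Removes MST edges longer than `theta`; the connected components of what
#' remains are the species.  With the default `theta = NULL` the threshold
#' comes from [species_threshold()] (largest relative gap in the
#' branch-length distribution), so a community without a clear two-level
#' structure is a single species.
#'
#' @inheritParams minimum_spanning_tree
#' @param mst_edges optional precomputed [minimum_spanning_tree()] edges.
#' @param theta branch-length threshold; `Inf` gives one species, `0`
#'   makes every distinct strain its own species.
#' @return An integer vector of species labels (1-based, in order of first
#'   member), one per row of `D`, with the threshold used in
#'   `attr(, "theta")`.
#' @export
cluster_species <- function(D, mst_edges = NULL, theta = NULL) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n == 0) stop("empty distance matrix")
  if (is.null(mst_edges)) mst_edges <- minimum_spanning_tree(D)
  if (is.null(theta)) theta <- species_threshold(mst_edges)
  keep <- mst_edges[mst_edges$weight <= theta, , drop = FALSE]
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(keep) > 0)
    g <- igraph::add_edges(g, rbind(keep$from, keep$to))
  comp <- igraph::components(g)$membership
  # relabel in order of first appearance for stable output
  lab <- match(comp, unique(comp))
  names(lab) <- rownames(D)
  attr(lab, "theta") <- theta
  lab
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Embeds a distance matrix in `k` dimensions by double-centring
#' \eqn{-D^2/2} and keeping the top-`k` eigenvectors scaled by the square
#' roots of their eigenvalues.  For a Euclidean-realisable `D` the
#' embedding reproduces the distances exactly once `k` reaches the
#' configuration's intrinsic dimension.  The embedding is unique only up to
#' rotation and reflection.
#'
#' @inheritParams minimum_spanning_tree
#' @param k target dimension (between 1 and `nrow(D) - 1`).
#' @return A list with `points` (n x k coordinate matrix), `eig`
#'   (eigenvalues) and `variance_fraction`: the fraction of the total
#'   positive eigenvalue mass captured by the `k` retained axes.
#' @export
cmds_embed <- function(D, k = 2) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2) stop("need at least two points to embed")
  if (k < 1 || k > n - 1) stop("target dimension k must be in [1, n - 1]")
  fit <- stats::cmdscale(stats::as.dist(D), k = k, eig = TRUE)
  pts <- fit$points
  if (ncol(pts) < k)  # degenerate configurations can drop trailing axes
    pts <- cbind(pts, matrix(0, n, k - ncol(pts)))
  pos <- pmax(fit$eig, 0)
  vf <- if (sum(pos) > 0) sum(pos[seq_len(k)]) / sum(pos) else 0
  list(points = pts, eig = fit$eig, variance_fraction = vf)
}

#' Snapshot diversity report
#'
#' Computes ten complementary diversity indices for one community snapshot,
#' covering richness (strain and species counts), evenness (Shannon,
#' Simpson, Pielou), functional diversity (MST size, mean pairwise trait
#' distance, dispersion around the trait centroid) and coarse functional
#' structure (number of functional groups, i.e. clusters at twice the
#' species threshold).
#'
#' @param snapshot a list with `abundance` (per-strain counts) and `matrix`
#'   (the interaction matrix at that time), as stored in
#'   `iteem_sim$snapshots`.
#' @param theta species branch-length threshold; `NULL` for the automatic
#'   choice ([species_threshold()]).
#' @return A one-row data frame with columns `strain_richness`,
#'   `species_richness`, `shannon_strains`, `shannon_species`,
#'   `pielou_evenness`, `simpson_index`, `smst`,
#'   `mean_pairwise_trait_distance`, `mean_distance_to_centroid` and
#'   `functional_group_count`.
#' @seealso [consensus_diversity()] for the sweep-normalised consensus.
#' @export
diversity_report <- function(snapshot, theta = NULL) {
  ab <- as.numeric(snapshot$abundance)
  m <- snapshot$matrix
  if (length(ab) == 0 || sum(ab) == 0) stop("empty snapshot")
  n <- length(ab)
  p <- ab / sum(ab)
  shannon <- function(q) as.numeric(vegan::diversity(q, index = "shannon"))
  simpson <- function(q) as.numeric(vegan::diversity(q, index = "simpson"))
  D <- trait_distances(m)
  mst_e <- minimum_spanning_tree(D)
  th <- if (is.null(theta)) species_threshold(mst_e) else theta
  sp <- cluster_species(D, mst_e, th)
  fg <- cluster_species(D, mst_e, if (is.finite(th)) 2 * th else Inf)
  sp_ab <- tapply(p, sp, sum)
  data.frame(
    strain_richness = n,
    species_richness = length(unique(sp)),
    shannon_strains = shannon(p),
    shannon_species = shannon(as.numeric(sp_ab)),
    pielou_evenness = if (n > 1) shannon(p) / log(n) else 0,
    simpson_index = simpson(p),
    smst = sum(mst_e$weight),
    mean_pairwise_trait_distance =
      if (n > 1) mean(D[upper.tri(D)]) else 0,
    mean_distance_to_centroid =
      if (n > 1) mean(sqrt(rowSums(sweep(m, 2, colMeans(m))^2))) else 0,
    functional_group_count = length(unique(fg)))
}

.diversity_index_names <- c(
  "strain_richness", "species_richness", "shannon_strains",
  "shannon_species", "pielou_evenness", "simpson_index", "smst",
  "mean_pairwise_trait_distance", "mean_distance_to_centroid",
  "functional_group_count")

#' Consensus diversity over a normalisation ensemble
#'
#' Min–max-normalises each of the ten indices of [diversity_report()] over
#' all rows of `reports` (the explicit normalisation ensemble, e.g. every
#' snapshot of every run of a sweep) and averages them per row.  An index
#' that is constant across the whole ensemble carries no information and is
#' mapped to 0.5 for every member.
#'
#' @param reports a data frame of stacked [diversity_report()] rows.
#' @return A numeric vector (one consensus value in \eqn{[0,1]} per row).
#' @export
consensus_diversity <- function(reports) {
  idx <- as.matrix(reports[, .diversity_index_names, drop = FALSE])
  rng <- apply(idx, 2, range)
  span <- rng[2, ] - rng[1, ]
  norm <- sweep(idx, 2, rng[1, ])
  norm <- sweep(norm, 2, ifelse(span > 0, span, 1), "/")
  norm[, span == 0] <- 0.5
  rowMeans(norm)
}
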