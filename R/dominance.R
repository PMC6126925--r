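#' Dominance network of a community
#'
#' The dominance network keeps, for every strain pair, only the superior
#' competitor's margin: the directed edge \eqn{\alpha \to \beta} has weight
#' \eqn{W_{\alpha\beta} = I_{\alpha\beta} - I_{\beta\alpha}} when
#' \eqn{I_{\alpha\beta} > I_{\beta\alpha}}, and \eqn{W_{\alpha\beta} = 0}
#' otherwise.  Exact ties (\eqn{I_{\alpha\beta} = 0.5}) produce no edge in
#' either direction.  All weights lie in \eqn{[0,1]} and at most one
#' direction per pair is nonzero.
#'
#' @param im an [interaction_matrix()] or plain reciprocal matrix with at
#'   least two strains (smaller communities give an edgeless network).
#' @return The weighted adjacency matrix `W` (class `dominance_network`),
#'   labelled like the input.
#' @export
build_dominance <- function(im) {
  m <- if (inherits(im, "interaction_matrix")) im$entries else im
  if (is.null(nrow(m)) || nrow(m) < 2) {
    W <- matrix(0, max(nrow(m), 0), max(nrow(m), 0), dimnames = dimnames(m))
    return(structure(W, class = c("dominance_network", "matrix")))
  }
  W <- m - t(m)
  W[W <= 0] <- 0
  diag(W) <- 0
  structure(W, class = c("dominance_network", "matrix"))
}

#' Aggregate a dominance network to species level
#'
#' The directed weight between species `i` and `j` is the mean of
#' \eqn{W_{\alpha\beta}} over *all* ordered pairs of member strains
#' (\eqn{\alpha \in i}, \eqn{\beta \in j}), zeros included; the
#' superior-competitor rule is then reapplied at species level (the larger
#' of the two directions is kept, the other set to zero; equal directions
#' cancel).
#'
#' @param W a `dominance_network` at strain level.
#' @param partition integer species labels, one per strain (e.g. from
#'   [cluster_species()]).
#' @return A species-level `dominance_network` (empty when the partition
#'   has a single species).
#' @export
species_dominance <- function(W, partition) {
  stopifnot(length(partition) == nrow(W))
  sp <- sort(unique(partition))
  k <- length(sp)
  S <- matrix(0, k, k, dimnames = list(sp, sp))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    S[i, j] <- mean(W[partition == sp[i], partition == sp[j], drop = FALSE])
  }
  keep <- S > t(S)
  S[!keep] <- 0
  structure(S, class = c("dominance_network", "matrix"))
}

#' Enumerate intransitive cycles
#'
#' Finds all simple directed cycles of length at most `max_len` in a
#' dominance network — length-3 cycles are rock–paper–scissors motifs: each
#' member beats one neighbour and loses to the other.  The *strength* of a
#' cycle is its weakest edge.
#'
#' @param W a `dominance_network` (or any nonnegative weighted adjacency
#'   matrix where positive entries are directed edges).
#' @param max_len maximal cycle length (default 3, the rock–paper–scissors
#'   motif; enumeration cost grows steeply beyond 5).
#' @return A data frame with columns `nodes` (list column of node index
#'   vectors), `length` and `strength`.
#' @export
enumerate_cycles <- function(W, max_len = 3) {
  stopifnot(max_len >= 3)
  if (max_len > 5)
    warning("simple-cycle enumeration beyond length 5 can be very costly")
  cyc <- .cycles_enumerate(unclass(as.matrix(W)), as.integer(max_len))
  if (length(cyc) == 0)
    return(data.frame(nodes = I(list()), length = integer(),
                      strength = numeric()))
  strength <- vapply(cyc, function(nodes) {
    nxt <- c(nodes[-1], nodes[1])
    min(W[cbind(nodes, nxt)])
  }, numeric(1))
  data.frame(nodes = I(cyc), length = lengths(cyc), strength = strength)
}

#' Cycle count and mean strength
#'
#' @inheritParams enumerate_cycles
#' @return A list with `count` and `mean_strength` (0 when there are no
#'   cycles); strengths average over cycles, not edges.
#' @export
cycle_stats <- function(W, max_len = 3) {
  if (max_len == 3) {
    s <- .cycle3_stats(unclass(as.matrix(W)))
    return(list(count = s[1], mean_strength = s[2]))
  }
  cyc <- enumerate_cycles(W, max_len)
  list(count = nrow(cyc),
       mean_strength = if (nrow(cyc)) mean(cyc$strength) else 0)
}

#' Randomised-ensemble baseline for cycle statistics
#'
#' Builds "equivalent random networks": the node set and the multiset of
#' pairwise weights are preserved, but weights are reshuffled across pairs
#' and each pair's direction is redrawn uniformly.  This destroys any
#' evolved structure while keeping the scale of the weights, so observed
#' cycle counts and strengths can be expressed in units of their
#' random-network expectation.
#'
#' @inheritParams enumerate_cycles
#' @param n_random ensemble size.
#' @return A list with `count_mean`, `count_sd`, `strength_mean`,
#'   `strength_sd` and `ensemble_size`.
#' @export
randomized_ensemble <- function(W, n_random = 100, max_len = 3) {
  stopifnot(n_random >= 1)
  W <- unclass(as.matrix(W))
  n <- nrow(W)
  up <- which(upper.tri(W), arr.ind = TRUE)
  pair_w <- W[up] + W[cbind(up[, 2], up[, 1])]  # at most one is nonzero
  counts <- numeric(n_random)
  strengths <- numeric(n_random)
  for (b in seq_len(n_random)) {
    w <- sample(pair_w)
    flip <- stats::runif(length(w)) < 0.5
    R <- matrix(0, n, n)
    R[up[!flip, , drop = FALSE]] <- w[!flip]
    R[cbind(up[flip, 2], up[flip, 1])] <- w[flip]
    s <- cycle_stats(R, max_len)
    counts[b] <- s$count
    strengths[b] <- s$mean_strength
  }
  list(count_mean = mean(counts), count_sd = stats::sd(counts),
       strength_mean = mean(strengths), strength_sd = stats::sd(strengths),
       ensemble_size = n_random)
}

#' Mean weight of dominance edges
#'
#' The average margin \eqn{\langle W \rangle} over the existing (nonzero)
#' directed edges; 0 for an edgeless network.  In structured communities
#' \eqn{\langle W \rangle} grows well beyond the mutation noise scale `m`,
#' whereas neutral drift keeps it at that scale.
#'
#' @inheritParams enumerate_cycles
#' @return A single number in \eqn{[0, 1]}.
#' @export
mean_edge_weight <- function(W) {
  w <- W[W > 0]
  if (length(w) == 0) return(0)
  mean(w)
}

#' Full dominance-network statistics of a snapshot
#'
#' Convenience wrapper computing \eqn{\langle W \rangle}, the cycle count
#' and mean cycle strength \eqn{\rho}, and their values normalised by a
#' randomised ensemble ([randomized_ensemble()]).
#'
#' @param im interaction matrix (or an `iteem_sim` snapshot's `matrix`).
#' @param n_random ensemble size for the normalisation (0 skips it).
#' @param max_len maximal cycle length.
#' @return A one-row data frame: `mean_W`, `n_cycles`, `mean_strength`,
#'   `normalized_count`, `normalized_strength` (NA when not normalised;
#'   observed/expected, with an expectation of 0 giving NA).
#' @export
network_stats <- function(im, n_random = 100, max_len = 3) {
  W <- build_dominance(im)
  cs <- cycle_stats(W, max_len)
  out <- data.frame(mean_W = mean_edge_weight(W), n_cycles = cs$count,
                    mean_strength = cs$mean_strength,
                    normalized_count = NA_real_,
                    normalized_strength = NA_real_)
  if (n_random > 0) {
    if (nrow(W) < 3 || cs$count == 0) {
      # a network without cycles has no cycle structure at all
      out$normalized_count <- 0
      out$normalized_strength <- 0
    } else {
      ens <- randomized_ensemble(W, n_random, max_len)
      out$normalized_count <-
        if (ens$count_mean > 0) cs$count / ens$count_mean else NA_real_
      out$normalized_strength <-
        if (ens$strength_mean > 0) cs$mean_strength / ens$strength_mean
        else NA_real_
    }
  }
  out
}
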