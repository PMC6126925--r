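# Independent brute-force oracles used to cross-check the implementation.

# Exhaustive minimum-spanning-tree weight: enumerate every labelled spanning
# tree of the complete graph on n nodes via Prufer sequences (n^(n-2) trees)
# and return the smallest total weight.
brute_mst_weight <- function(D) {
  n <- nrow(D)
  if (n <= 1) return(0)
  if (n == 2) return(D[1, 2])
  tree_weight <- function(pr) {
    deg <- rep(1L, n)
    for (v in pr) deg[v] <- deg[v] + 1L
    w <- 0
    for (v in pr) {
      leaf <- which(deg == 1L)[1]
      w <- w + D[leaf, v]
      deg[leaf] <- 0L
      deg[v] <- deg[v] - 1L
    }
    ends <- which(deg == 1L)
    w + D[ends[1], ends[2]]
  }
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- Inf
  for (i in seq_len(nrow(seqs)))
    best <- min(best, tree_weight(seqs[i, ]))
  best
}

# Brute-force directed 3-cycle enumeration: check both cyclic orientations
# of every node triple.
brute_cycles3 <- function(W) {
  n <- nrow(W)
  out <- list()
  if (n < 3) return(out)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    if (W[i, j] > 0 && W[j, k] > 0 && W[k, i] > 0)
      out <- c(out, list(c(i, j, k)))
    if (W[i, k] > 0 && W[k, j] > 0 && W[j, i] > 0)
      out <- c(out, list(c(i, k, j)))
  }
  out
}

# Brute-force simple directed cycles of length 3..max_len: for every node
# subset, try all cyclic orders (first element anchored to kill rotations).
brute_simple_cycles <- function(W, max_len) {
  n <- nrow(W)
  out <- list()
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  for (L in 3:max_len) {
    if (L > n) break
    for (sub in utils::combn(n, L, simplify = FALSE)) {
      a <- sub[1]
      for (rest in perms(sub[-1])) {
        cyc <- c(a, rest)
        nxt <- c(cyc[-1], cyc[1])
        if (all(W[cbind(cyc, nxt)] > 0)) out <- c(out, list(cyc))
      }
    }
  }
  out
}

# Canonical form for comparing cycle sets: rotate so the smallest node
# leads, then sort lexicographically.
canon_cycles <- function(cycles) {
  if (length(cycles) == 0) return(character(0))
  sort(vapply(cycles, function(cyc) {
    i <- which.min(cyc)
    paste(c(cyc[i:length(cyc)], cyc[seq_len(i - 1)]), collapse = "-")
  }, character(1)))
}

# A small hand-checkable reciprocal matrix: two near-identical strains plus
# one outlier, used across lineage/metrics tests.
two_cluster_matrix <- function() {
  m <- matrix(c(0.5, 0.5, 0.9,
                0.5, 0.5, 0.9,
                0.1, 0.1, 0.5), 3, 3, byrow = TRUE)
  dimnames(m) <- list(c("0", "1", "2"), c("0", "1", "2"))
  m
}
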