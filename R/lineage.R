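#' Strain genealogy of a run
#'
#' Validates and returns the lineage table of a simulation: one row per
#' strain ever established, with its `id` (stable handle), `parent`
#' (`NA`/-1 for the founder), birth generation `t_birth` and extinction
#' generation `t_extinct` (`NA` while alive).  Mutant offspring that lost
#' their very first contest never founded a strain and do not appear.
#'
#' @param x an `iteem_sim` object, or a data frame with columns `id`,
#'   `parent`, `t_birth`, `t_extinct`.
#' @return A `lineage_tree` data frame.
#' @export
lineage_tree <- function(x) {
  lin <- if (inherits(x, "iteem_sim")) x$lineage else as.data.frame(x)
  stopifnot(all(c("id", "parent", "t_birth", "t_extinct") %in% names(lin)))
  if (nrow(lin) == 0) stop("empty lineage")
  lin$parent[lin$parent < 0] <- NA_integer_
  roots <- which(is.na(lin$parent))
  if (length(roots) != 1) stop("lineage must have exactly one founder")
  nonroot <- lin[!is.na(lin$parent), , drop = FALSE]
  if (nrow(nonroot) > 0) {
    pi <- match(nonroot$parent, lin$id)
    if (anyNA(pi)) stop("lineage refers to unknown parent strains")
    if (any(lin$t_birth[pi] > nonroot$t_birth))
      stop("a parent cannot be born after its child")
  }
  class(lin) <- c("lineage_tree", "data.frame")
  lin
}

#' Export a lineage as a Newick phylogeny
#'
#' Serialises the strain genealogy as a Newick string with branch lengths
#' in generations.  Each strain contributes one leaf (its terminal
#' segment); internal nodes are the mutation events along ancestral
#' strains, so a strain that begat children appears as a path of internal
#' nodes ending in its own leaf.  A strain's terminal segment ends at its
#' extinction or, if still alive, at `t_end`.  With `live_only = TRUE`
#' extinct leaves are pruned (unary internal nodes are collapsed and their
#' branch lengths merged).
#'
#' @param tree a [lineage_tree()] (or an `iteem_sim`).
#' @param t_end end-of-observation generation used for open branches;
#'   defaults to the largest time in the table.
#' @param live_only drop strains already extinct at `t_end`?
#' @return A Newick string (parseable by standard phylogeny readers, e.g.
#'   `ape::read.tree`).
#' @export
to_newick <- function(tree, t_end = NULL, live_only = FALSE) {
  lin <- lineage_tree(tree)
  if (is.null(t_end))
    t_end <- max(c(lin$t_birth, lin$t_extinct), na.rm = TRUE)
  alive <- is.na(lin$t_extinct)
  term <- ifelse(alive, t_end, lin$t_extinct)
  kids <- split(seq_len(nrow(lin)), factor(lin$parent, levels = lin$id))
  keep <- rep(TRUE, nrow(lin))
  if (live_only) {
    # a row is kept if it is alive or has a kept descendant
    ord <- order(lin$t_birth, decreasing = TRUE)
    keep <- alive
    for (i in ord) {
      if (keep[i] && !is.na(lin$parent[i]))
        keep[match(lin$parent[i], lin$id)] <- TRUE
    }
    if (!any(keep)) stop("no live strains at t_end")
  }
  # Children are processed before their parents (sort by lineage depth),
  # then each strain's node string is folded iteratively over its ordered
  # mutation events, so arbitrarily deep genealogies serialise without
  # recursion.  Per strain the subtree is a chain: at each child birth the
  # branch bifurcates into (continuation, child subtree); the terminal
  # segment is the strain's own leaf.  Unary nodes left by pruning are
  # collapsed by accumulating branch length.
  n <- nrow(lin)
  pidx <- match(lin$parent, lin$id)
  depth <- integer(n)
  ord <- order(lin$t_birth)        # parents precede children
  for (i in ord) if (!is.na(pidx[i])) depth[i] <- depth[pidx[i]] + 1L
  node_str <- character(n)         # subtree string without root length
  node_len <- numeric(n)           # its root branch length
  node_ok <- logical(n)
  fmt <- function(s, l) sprintf("%s:%s", s, format(l))
  for (i in order(depth, decreasing = TRUE)) {
    if (!keep[i]) next
    cs <- kids[[as.character(lin$id[i])]]
    cs <- cs[keep[cs] & node_ok[cs]]
    cs <- cs[order(lin$t_birth[cs])]
    leaf_ok <- !live_only || alive[i]
    # fold from the terminal segment backwards over child births
    t_prev <- if (length(cs)) lin$t_birth[cs[length(cs)]] else lin$t_birth[i]
    if (leaf_ok) {
      cur_str <- as.character(lin$id[i])
      cur_len <- term[i] - t_prev
      have <- TRUE
    } else {
      cur_str <- ""
      cur_len <- 0
      have <- FALSE
    }
    for (j in rev(seq_along(cs))) {
      cj <- cs[j]
      t_from <- if (j > 1) lin$t_birth[cs[j - 1]] else lin$t_birth[i]
      seg <- lin$t_birth[cj] - t_from
      if (have) {
        cur_str <- sprintf("(%s,%s)", fmt(cur_str, cur_len),
                           fmt(node_str[cj], node_len[cj]))
        cur_len <- seg
      } else {                      # unary: extend the child's branch
        cur_str <- node_str[cj]
        cur_len <- node_len[cj] + seg
        have <- TRUE
      }
    }
    node_str[i] <- cur_str
    node_len[i] <- cur_len
    node_ok[i] <- have
  }
  root_i <- which(is.na(lin$parent))
  if (!node_ok[root_i]) stop("no strains to serialise")
  sprintf("(%s);", fmt(node_str[root_i], node_len[root_i]))
}

.ancestor_in <- function(id, parent_of, universe) {
  # most recent ancestor (possibly id itself) contained in `universe`
  h <- id
  while (!is.na(h) && !(h %in% universe))
    h <- parent_of[[as.character(h)]]
  h
}

#' Track species across snapshots
#'
#' Clusters every snapshot into species ([cluster_species()] on the
#' trait-distance matrix) and chains the per-snapshot partitions into
#' persistent species labels: a species at snapshot \eqn{k+1} is linked to
#' the species at snapshot \eqn{k} that contains its members' ancestors
#' (majority rule by abundance).  When several species link to the same
#' predecessor, the most abundant one keeps the label and the others
#' become its children — this is what makes species colours stable in a
#' Muller plot.
#'
#' @param sim an `iteem_sim` with recorded snapshots.
#' @param theta species threshold passed to [cluster_species()] (`NULL`
#'   for automatic).
#' @return A list with `labels` (per snapshot, an integer vector of
#'   persistent species ids aligned with the snapshot's strains),
#'   `parents` (named vector: species id -> parent species id, `NA` for
#'   roots) and `generations`.
#' @export
track_species <- function(sim, theta = NULL) {
  stopifnot(inherits(sim, "iteem_sim"))
  snaps <- sim$snapshots
  if (length(snaps) == 0) stop("simulation has no snapshots")
  lin <- sim$lineage
  parent_of <- as.list(stats::setNames(
    ifelse(lin$parent < 0, NA_integer_, lin$parent), lin$id))
  labels <- vector("list", length(snaps))
  parents <- integer(0)
  next_id <- 1L
  prev_handles <- NULL
  prev_labels <- NULL
  for (k in seq_along(snaps)) {
    sn <- snaps[[k]]
    handles <- as.integer(sn$handles)
    ab <- as.numeric(sn$abundance)
    part <- if (length(handles) == 1) {
      structure(1L, names = as.character(handles))
    } else {
      cluster_species(trait_distances(sn$matrix), theta = theta)
    }
    k_sp <- sort(unique(part))
    glob <- integer(length(part))
    if (k == 1) {
      for (s in k_sp) {
        glob[part == s] <- next_id
        parents[as.character(next_id)] <- NA_integer_
        next_id <- next_id + 1L
      }
    } else {
      # majority-ancestry link of each current species to a previous label
      link <- integer(length(k_sp))
      size <- numeric(length(k_sp))
      for (si in seq_along(k_sp)) {
        mem <- which(part == k_sp[si])
        votes <- numeric(0)
        for (ix in mem) {
          anc <- .ancestor_in(handles[ix], parent_of, prev_handles)
          if (is.na(anc))
            stop("species has no lineage link to the previous snapshot")
          lab <- as.character(prev_labels[match(anc, prev_handles)])
          votes[lab] <- (if (is.na(votes[lab])) 0 else votes[lab]) + ab[ix]
        }
        link[si] <- as.integer(names(votes)[which.max(votes)])
        size[si] <- sum(ab[mem])
      }
      for (L in unique(link)) {
        grp <- which(link == L)
        main <- grp[which.max(size[grp])]
        glob[part == k_sp[main]] <- L
        for (si in setdiff(grp, main)) {
          glob[part == k_sp[si]] <- next_id
          parents[as.character(next_id)] <- L
          next_id <- next_id + 1L
        }
      }
    }
    labels[[k]] <- glob
    prev_handles <- handles
    prev_labels <- glob
  }
  list(labels = labels, parents = parents,
       generations = as.integer(sim$snapshot_generations))
}

#' Muller-plot tables
#'
#' Produces the two-table format consumed by common Muller-plot tools: an
#' *adjacency* table of parent/child species and a *population* table of
#' relative species abundances per recorded generation.  Species identity
#' over time comes from [track_species()].
#'
#' @inheritParams track_species
#' @param tracking optional precomputed [track_species()] result.
#' @return A list with data frames `adjacency` (`parent`, `child`) and
#'   `population` (`generation`, `species`, `abundance`); per generation
#'   the relative abundances sum to 1.
#' @export
muller_table <- function(sim, theta = NULL, tracking = NULL) {
  tr <- if (is.null(tracking)) track_species(sim, theta) else tracking
  rows <- list()
  for (k in seq_along(tr$labels)) {
    sn <- sim$snapshots[[k]]
    ab <- as.numeric(sn$abundance)
    rel <- ab / sum(ab)
    agg <- tapply(rel, tr$labels[[k]], sum)
    rows[[k]] <- data.frame(generation = tr$generations[k],
                            species = as.integer(names(agg)),
                            abundance = as.numeric(agg))
  }
  pop <- do.call(rbind, rows)
  par <- tr$parents
  adj <- data.frame(parent = as.integer(par), child = as.integer(names(par)))
  adj <- adj[!is.na(adj$parent), , drop = FALSE]
  rownames(adj) <- NULL
  list(adjacency = adj, population = pop)
}

#' Write the lineage table as TSV
#'
#' @inheritParams to_newick
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_lineage <- function(tree, path) {
  lin <- lineage_tree(tree)
  utils::write.table(as.data.frame(lin), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
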