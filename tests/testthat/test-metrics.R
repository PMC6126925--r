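test_that("trait distances exclude the mutual coordinates and obey metric axioms", {
  m <- two_cluster_matrix()
  D <- trait_distances(m)
  # hand value: rows 1 and 3 differ only at the third-party coordinate 2
  expect_equal(D[1, 3], 0.4)
  expect_equal(D[2, 3], 0.4)
  expect_equal(D[1, 2], 0)      # identical behaviour towards strain 3
  # independent elementwise oracle on a random community
  set.seed(10)
  im <- random_reciprocal_matrix(10)
  E <- im$entries
  D10 <- trait_distances(im)
  for (a in 1:10) for (b in 1:10) {
    others <- setdiff(1:10, c(a, b))
    expect_equal(D10[a, b], sqrt(sum((E[a, others] - E[b, others])^2)),
                 tolerance = 1e-12)
  }
  expect_equal(D10, t(D10))
  expect_equal(unname(diag(D10)), rep(0, 10))
  # two-strain fallback: |I12 - I21| / sqrt(2)
  m2 <- matrix(c(0.5, 0.8, 0.2, 0.5), 2, 2, byrow = TRUE)
  expect_equal(trait_distances(m2)[1, 2], abs(0.8 - 0.2) / sqrt(2))
})

test_that("the minimum spanning tree matches exhaustive enumeration", {
  D <- matrix(c(0, 1, 3,
                1, 0, 2,
                3, 2, 0), 3, 3, byrow = TRUE)
  e <- minimum_spanning_tree(D)
  expect_equal(nrow(e), 2)
  expect_equal(smst(D), 3)
  key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
  expect_setequal(key, c("1 2", "2 3"))
  # single point: no edges, zero size
  expect_equal(nrow(minimum_spanning_tree(matrix(0, 1, 1))), 0)
  expect_equal(smst(matrix(0, 1, 1)), 0)
  # random fixtures vs brute force over all labelled spanning trees
  set.seed(3)
  for (n in c(4, 5, 6)) {
    for (rep in 1:3) {
      pts <- matrix(stats::runif(n * 3), n, 3)
      D <- as.matrix(stats::dist(pts))
      expect_equal(smst(D), brute_mst_weight(D), tolerance = 1e-12)
    }
  }
})

test_that("duplicated strains never change the MST size", {
  set.seed(4)
  pts <- matrix(stats::runif(18), 6, 3)
  D <- as.matrix(stats::dist(pts))
  D2 <- as.matrix(stats::dist(pts[c(1:6, 4), ]))  # point 4 duplicated
  expect_equal(smst(D2), smst(D), tolerance = 1e-12)
})

test_that("species clustering cuts the long branches", {
  set.seed(6)
  pts <- planted_cluster_traits(3, spread = 0.02, separation = 0.5,
                                n_per = 6)
  D <- as.matrix(stats::dist(pts))
  truth <- attr(pts, "cluster")
  for (theta in c(0.15, 0.25, 0.35)) {
    sp <- cluster_species(D, theta = theta)
    expect_equal(length(unique(sp)), 3)
    # recovered partition refines to the planted one
    expect_true(all(tapply(truth, sp, function(v) length(unique(v))) == 1))
  }
  # automatic threshold finds the same split
  sp_auto <- cluster_species(D)
  expect_equal(length(unique(sp_auto)), 3)
  # threshold extremes
  expect_equal(length(unique(cluster_species(D, theta = Inf))), 1)
  expect_equal(length(unique(cluster_species(D, theta = 0))), nrow(D))
})

test_that("classical MDS recovers realisable configurations", {
  # collinear points with gaps 1, 1
  D <- matrix(c(0, 1, 2,
                1, 0, 1,
                2, 1, 0), 3, 3, byrow = TRUE)
  em <- cmds_embed(D, k = 1)
  got <- as.matrix(stats::dist(em$points))
  expect_equal(got, D, tolerance = 1e-9, ignore_attr = TRUE)
  # exactly planar 5-point configuration embeds losslessly in k = 2
  set.seed(12)
  xy <- matrix(stats::runif(10), 5, 2)
  D5 <- as.matrix(stats::dist(xy))
  em5 <- cmds_embed(D5, k = 2)
  expect_equal(as.matrix(stats::dist(em5$points)), D5,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(em5$variance_fraction, 1, tolerance = 1e-9)
  expect_error(cmds_embed(D5, k = 5), "k")
})

test_that("diversity indices hit their closed forms", {
  mono <- list(abundance = 7, matrix = matrix(0.5, 1, 1))
  r1 <- diversity_report(mono)
  expect_equal(r1$strain_richness, 1)
  expect_equal(r1$shannon_strains, 0)
  expect_equal(r1$simpson_index, 0)
  expect_equal(r1$smst, 0)
  expect_equal(r1$pielou_evenness, 0)
  two <- list(abundance = c(5, 5),
              matrix = matrix(c(0.5, 0.6, 0.4, 0.5), 2, 2, byrow = TRUE))
  r2 <- diversity_report(two)
  expect_equal(r2$shannon_strains, log(2))
  expect_equal(r2$pielou_evenness, 1)
  expect_equal(r2$simpson_index, 0.5)
  expect_error(diversity_report(list(abundance = numeric(),
                                     matrix = matrix(0, 0, 0))), "empty")
})

test_that("Shannon and Simpson are maximal at uniform abundances", {
  set.seed(8)
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  S <- function(p) 1 - sum(p^2)
  for (k in c(3, 5, 9)) {
    unif <- rep(1 / k, k)
    for (rep in 1:10) {
      p <- stats::runif(k); p <- p / sum(p)
      expect_lte(H(p), H(unif) + 1e-12)
      expect_lte(S(p), S(unif) + 1e-12)
    }
  }
})

test_that("consensus diversity normalises over the stated ensemble", {
  snaps <- list(
    list(abundance = 10, matrix = matrix(0.5, 1, 1)),
    list(abundance = c(5, 5),
         matrix = matrix(c(0.5, 0.6, 0.4, 0.5), 2, 2, byrow = TRUE)),
    list(abundance = c(4, 3, 3), matrix = two_cluster_matrix()))
  reps <- do.call(rbind, lapply(snaps, diversity_report))
  cons <- consensus_diversity(reps)
  expect_true(all(cons >= 0 & cons <= 1))
  # monomorphic < diverse three-strain snapshot
  expect_lt(cons[1], cons[3])
  # degenerate ensemble of identical snapshots: all indices constant -> 0.5
  same <- do.call(rbind, lapply(1:3, function(i) diversity_report(snaps[[2]])))
  expect_equal(consensus_diversity(same), rep(0.5, 3))
})
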