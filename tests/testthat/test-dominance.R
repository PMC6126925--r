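test_that("dominance edges keep only the superior competitor's margin", {
  m <- matrix(c(0.5, 0.7, 0.3, 0.5), 2, 2, byrow = TRUE)
  W <- build_dominance(m)
  expect_equal(W[1, 2], 0.4)
  expect_equal(W[2, 1], 0)
  # perfect ties produce no edges and <W> falls back to 0
  tied <- build_dominance(matrix(0.5, 4, 4))
  expect_true(all(tied == 0))
  expect_equal(mean_edge_weight(tied), 0)
  # antisymmetry on random communities
  set.seed(2)
  for (rep in 1:5) {
    Wr <- build_dominance(random_reciprocal_matrix(8))
    expect_true(all(Wr * t(Wr) == 0))
    expect_true(all(Wr >= 0 & Wr <= 1))
  }
})

test_that("species-level aggregation averages over all member pairs", {
  W <- matrix(0, 3, 3)
  W[1, 3] <- 0.2  # strains 1, 2 form species i; strain 3 is species j
  W[2, 3] <- 0.4
  S <- species_dominance(structure(W, class = c("dominance_network",
                                                "matrix")),
                         partition = c(1, 1, 2))
  expect_equal(S[1, 2], 0.3)
  expect_equal(S[2, 1], 0)
  # two singleton species: the species edge equals the strain edge
  W2 <- matrix(c(0, 0.25, 0, 0), 2, 2, byrow = TRUE)
  S2 <- species_dominance(structure(W2, class = c("dominance_network",
                                                  "matrix")), c(1, 2))
  expect_equal(S2[1, 2], 0.25)
  # one species swallowing everything gives an empty network
  S1 <- species_dominance(structure(W, class = c("dominance_network",
                                                 "matrix")), c(1, 1, 1))
  expect_equal(dim(S1), c(1L, 1L))
  expect_true(all(S1 == 0))
})

test_that("cycle enumeration matches brute force on tournaments", {
  # planted rock-paper-scissors
  W <- planted_cycle_network(c(0.2, 0.5, 0.4))
  cyc <- enumerate_cycles(W)
  expect_equal(nrow(cyc), 1)
  expect_equal(cyc$strength, 0.2)
  # transitive tournament: no cycles
  Wt <- matrix(0, 3, 3); Wt[1, 2] <- 0.3; Wt[1, 3] <- 0.2; Wt[2, 3] <- 0.1
  expect_equal(nrow(enumerate_cycles(Wt)), 0)
  expect_equal(cycle_stats(Wt)$count, 0)
  # random 7-node tournaments vs exhaustive triple enumeration
  set.seed(5)
  for (rep in 1:10) {
    W7 <- unclass(random_tournament(7))
    got <- enumerate_cycles(W7, max_len = 3)
    want <- brute_cycles3(W7)
    expect_equal(canon_cycles(got$nodes), canon_cycles(want))
    cs <- cycle_stats(W7)
    expect_equal(cs$count, length(want))
    if (length(want) > 0) {
      want_str <- vapply(want, function(cyc)
        min(W7[cbind(cyc, c(cyc[-1], cyc[1]))]), numeric(1))
      expect_equal(sort(got$strength), sort(want_str))
      expect_equal(cs$mean_strength, mean(want_str))
    }
  }
})

test_that("longer simple cycles are enumerated correctly", {
  set.seed(9)
  for (rep in 1:5) {
    W <- matrix(stats::runif(36), 6, 6)
    W[W < 0.55] <- 0   # sparse digraph, both directions possible
    diag(W) <- 0
    for (L in 4:5) {
      got <- enumerate_cycles(W, max_len = L)
      want <- brute_simple_cycles(W, L)
      expect_equal(canon_cycles(got$nodes), canon_cycles(want))
    }
  }
  # a planted 4-cycle is found at max_len 4 but not at 3
  W4 <- planted_cycle_network(c(0.3, 0.2, 0.5, 0.4))
  expect_equal(nrow(enumerate_cycles(W4, max_len = 3)), 0)
  c4 <- enumerate_cycles(W4, max_len = 4)
  expect_equal(nrow(c4), 1)
  expect_equal(c4$strength, 0.2)
})

test_that("the randomised ensemble reproduces exact orientation statistics", {
  # 3 nodes, all pairs weighted: of the 8 equally likely orientations,
  # exactly 2 are cyclic, so the expected cycle count is 1/4
  W <- build_dominance(random_reciprocal_matrix(3))
  set.seed(11)
  ens <- randomized_ensemble(W, n_random = 2000)
  se <- sqrt(0.25 * 0.75 / 2000)
  expect_lt(abs(ens$count_mean - 0.25), 4 * se)
  # edgeless input: ensemble counts are all zero
  ens0 <- randomized_ensemble(structure(matrix(0, 4, 4),
                                        class = c("dominance_network",
                                                  "matrix")),
                              n_random = 50)
  expect_equal(ens0$count_mean, 0)
  expect_equal(ens0$strength_mean, 0)
})

test_that("a random tournament is self-consistent under normalisation", {
  set.seed(21)
  W <- random_tournament(10)
  st <- network_stats(W, n_random = 300)
  # the observed network is itself a draw from the ensemble
  expect_gt(st$normalized_count, 0.5)
  expect_lt(st$normalized_count, 1.6)
  expect_gt(st$normalized_strength, 0.5)
  expect_lt(st$normalized_strength, 1.6)
})

test_that("mean edge weight averages the existing edges", {
  W <- matrix(0, 3, 3); W[1, 2] <- 0.4
  expect_equal(mean_edge_weight(W), 0.4)
  W[2, 3] <- 0.2
  expect_equal(mean_edge_weight(W), 0.3)
})
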