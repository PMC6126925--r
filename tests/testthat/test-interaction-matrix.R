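test_that("the founder community is a single strain with zero competitive ability", {
  im <- create_founder()
  expect_equal(n_strains(im), 1L)
  expect_equal(unname(im$entries), matrix(0.5, 1, 1))
  expect_equal(competitive_ability(im, im$handles[1]), 0)
  expect_equal(reciprocity_residual(im), 0)
})

test_that("mutants inherit the parental trait with exact reciprocal bookkeeping", {
  set.seed(42)
  im <- create_founder()
  for (k in 1:6) im <- add_mutant(im, im$handles[sample.int(n_strains(im), 1)], m = 0.02)
  expect_equal(n_strains(im), 7L)
  expect_equal(unname(diag(im$entries)), rep(0.5, 7))
  expect_identical(reciprocity_residual(im), 0)
  expect_true(all(im$entries >= 0 & im$entries <= 1))

  # near-zero noise: the child row is a copy of the parent row, the
  # child-parent entry is the parent's (perturbed) self-survival 0.5
  im2 <- add_mutant(im, parent = im$handles[3], m = 1e-12)
  h <- attr(im2, "new_handle")
  i_new <- match(h, im2$handles)
  others <- setdiff(seq_len(n_strains(im2)), c(i_new, 3))
  expect_equal(unname(im2$entries[i_new, others]),
               unname(im2$entries[3, others]), tolerance = 1e-9)
  expect_equal(unname(im2$entries[i_new, i_new]), 0.5)
  expect_equal(unname(im2$entries[i_new, 3]), 0.5, tolerance = 1e-9)
})

test_that("clipping keeps entries in [0,1] and reciprocity exact even at huge noise", {
  set.seed(7)
  im <- create_founder()
  for (k in 1:20) im <- add_mutant(im, im$handles[sample.int(n_strains(im), 1)], m = 10)
  expect_true(all(im$entries >= 0 & im$entries <= 1))
  expect_identical(reciprocity_residual(im), 0)
  expect_equal(unname(diag(im$entries)), rep(0.5, n_strains(im)))
})

test_that("removing a strain preserves all other entries and retires the handle", {
  set.seed(1)
  im <- create_founder()
  im <- add_mutant(im, 0, m = 0.1)
  im <- add_mutant(im, 0, m = 0.1)
  mid <- im$handles[2]
  survivors <- setdiff(im$handles, mid)
  before <- im$entries[as.character(survivors), as.character(survivors)]
  im2 <- remove_strain(im, mid)
  expect_equal(im2$handles, survivors)
  expect_identical(im2$entries, before)
  # the handle is retired for every operation
  expect_error(competitive_ability(im2, mid), "unknown or retired")
  expect_error(remove_strain(im2, mid), "unknown or retired")
  expect_error(add_mutant(im2, mid, 0.02), "unknown or retired")
  # removing everything leaves a well-formed empty community
  for (h in survivors) im2 <- remove_strain(im2, h)
  expect_equal(n_strains(im2), 0L)
  expect_equal(dim(im2$entries), c(0L, 0L))
})

test_that("competitive ability is the mean off-diagonal row entry", {
  m <- rbind(c(0.5, 0.6, 0.8),
             c(0.4, 0.5, 0.3),
             c(0.2, 0.7, 0.5))
  dimnames(m) <- list(0:2, 0:2)
  im <- interaction_matrix(m)
  expect_equal(competitive_ability(im, 0), 0.7)
  expect_equal(competitive_ability(im, 1), 0.35)
  expect_equal(competitive_ability(im, 2), 0.45)
  # all off-diagonal entries 0.5 -> C = 0.5
  im5 <- interaction_matrix(`dimnames<-`(matrix(0.5, 4, 4),
                                         list(0:3, 0:3)))
  for (h in im5$handles) expect_equal(competitive_ability(im5, h), 0.5)
})

test_that("the reciprocity residual flags hand-corrupted entries", {
  im <- random_reciprocal_matrix(4)
  expect_identical(reciprocity_residual(im), 0)
  im$entries[1, 2] <- 0.7
  im$entries[2, 1] <- 0.4
  expect_equal(reciprocity_residual(im), 0.1)
})

test_that("invariants survive long random mutate/remove sequences", {
  set.seed(2024)
  im <- create_founder()
  n_ops <- 10000
  for (k in seq_len(n_ops)) {
    if (n_strains(im) == 1 || stats::runif(1) < 0.5) {
      im <- add_mutant(im, im$handles[sample.int(n_strains(im), 1)], m = 0.05)
    } else {
      im <- remove_strain(im, im$handles[sample.int(n_strains(im), 1)])
    }
  }
  expect_identical(reciprocity_residual(im), 0)
  expect_true(all(im$entries >= 0 & im$entries <= 1))
  expect_equal(unname(diag(im$entries)), rep(0.5, n_strains(im)))
  expect_equal(anyDuplicated(im$handles), 0L)
})

test_that("mutation noise is heritable and unbiased", {
  # mid-range parent row so clipping is negligible
  set.seed(99)
  n <- 6
  m0 <- matrix(stats::runif(n * n, 0.35, 0.65), n, n)
  m0[lower.tri(m0)] <- 1 - t(m0)[lower.tri(m0)]
  diag(m0) <- 0.5
  dimnames(m0) <- list(seq_len(n) - 1, seq_len(n) - 1)
  im <- interaction_matrix(m0)
  parent <- 2
  width <- 0.02
  n_mut <- 10000
  dev <- matrix(NA_real_, n_mut, n)
  for (k in seq_len(n_mut)) {
    child <- add_mutant(im, parent, m = width)
    i_new <- n_strains(child)
    dev[k, ] <- child$entries[i_new, seq_len(n)] -
      im$entries[parent + 1, seq_len(n)]
  }
  se <- width / sqrt(length(dev))
  expect_lt(abs(mean(dev)), 4 * se)
})

test_that("matrix snapshots round-trip through TSV", {
  set.seed(5)
  im <- create_founder()
  for (k in 1:6) im <- add_mutant(im, im$handles[sample.int(n_strains(im), 1)], m = 0.05)
  im <- remove_strain(im, im$handles[3])
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_snapshot(im, path)
  back <- read_matrix_snapshot(path)
  expect_equal(back$handles, im$handles)
  expect_equal(back$entries, im$entries, tolerance = 1e-10)
  expect_identical(reciprocity_residual(back), 0)
})
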