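test_that("identical seeds give bit-identical trajectories", {
  cfg <- sim_config(ns = 300, delta = 0.5, lambda = 40, mu = 5e-3, m = 0.02,
                    generations = 400, seed = 123, record_every = 100)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$summary, b$summary)
  expect_identical(a$lineage, b$lineage)
  expect_identical(a$final$matrix, b$final$matrix)
  expect_identical(a$final$site_strain, b$final$site_strain)
})

test_that("the stepping interface reproduces the fast path exactly", {
  cfg <- sim_config(ns = 120, delta = 0.5, lambda = 30, mu = 0.01, m = 0.02,
                    generations = 3, seed = 77, record_every = 1)
  fast <- run_simulation(cfg)
  set.seed(cfg$seed)
  eng <- engine_start(cfg)
  for (g in 1:3) {
    engine_next_generation(eng)
    for (k in seq_len(cfg$ns)) engine_trial(eng)
    engine_death_step(eng)
  }
  st <- engine_state(eng)
  expect_identical(st$matrix, fast$final$matrix)
  expect_identical(st$site_strain, fast$final$site_strain)
  expect_equal(st$n_individuals, fast$final$n_individuals)
})

test_that("bookkeeping is conserved and the roster matches the matrix", {
  cfg <- sim_config(ns = 500, delta = 0.4, lambda = 25, mu = 5e-3, m = 0.02,
                    generations = 600, seed = 9, record_every = 200)
  sim <- run_simulation(cfg)
  expect_true(all(sim$summary$n_individuals <= cfg$ns))
  st <- sim$final
  # abundance recomputed from the sites equals the cached abundance
  occ <- st$site_strain[st$site_strain >= 0]
  counted <- table(factor(occ, levels = st$handles))
  expect_equal(as.numeric(counted), as.numeric(st$abundance))
  expect_equal(sum(st$abundance), st$n_individuals)
  expect_true(all(st$abundance >= 1))
  # live roster equals matrix dimension; cached r matches the trade-off
  expect_equal(length(st$handles), nrow(st$matrix))
  expect_equal(st$replication_prob,
               replication_probability(st$competitive_ability, cfg$delta))
  # snapshots preserve exact reciprocity and the 0.5 diagonal
  for (sn in sim$snapshots) {
    M <- sn$matrix
    if (nrow(M) >= 2) expect_identical(max(abs(M + t(M) - 1)), 0)
    expect_identical(unname(diag(M)), rep(0.5, nrow(M)))
  }
})

test_that("contests follow the survival probability exactly and in law", {
  # deterministic case: offspring with survival probability 1 always kills
  I2 <- matrix(c(0.5, 1.0,
                 0.0, 0.5), 2, 2, byrow = TRUE)
  cfg <- sim_config(ns = 100, delta = 0.5, lambda = Inf, mu = 0,
                    generations = 500, seed = 31, record_every = 500)
  sim <- run_simulation(cfg, init = list(matrix = I2, abundance = c(1, 99),
                                         r = c(1, 0)))
  # only strain 0 replicates and it wins every contest: strain 1 must go
  expect_equal(sim$final$handles, 0L)
  expect_false(is.na(sim$lineage$t_extinct[2]))
  # binomial case: fair coin within 3 standard errors
  set.seed(4)
  n <- 10000
  wins <- neutral_contest(n)
  se <- sqrt(0.25 / n)
  expect_lt(abs(wins / n - 0.5), 3 * se)
  expect_equal(neutral_contest(200, p = 1), 200)
  expect_equal(neutral_contest(200, p = 0), 0)
})

test_that("without mutation the strain roster can only shrink", {
  I3 <- random_reciprocal_matrix(3)$entries
  cfg <- sim_config(ns = 300, delta = 0.5, lambda = 20, mu = 0,
                    generations = 400, seed = 8, record_every = 100)
  sim <- run_simulation(cfg, init = list(matrix = I3,
                                         abundance = c(100, 100, 100)))
  expect_true(all(diff(sim$summary$n_strains) <= 0))
  expect_true(all(sim$summary$mutations == 0))
})

test_that("the death step enforces lifespans", {
  # lambda = Inf: no lifespan deaths ever
  cfg <- sim_config(ns = 200, delta = 0.5, lambda = Inf, mu = 1e-3, m = 0.02,
                    generations = 300, seed = 5, record_every = 100)
  sim <- run_simulation(cfg)
  expect_true(all(sim$summary$deaths_lifespan == 0))
  # lambda ~ 0: every newborn draws lifespan 0 and dies in its birth
  # generation's death step; the community collapses immediately
  cfg0 <- sim_config(ns = 200, delta = 0, lambda = 1e-9, mu = 0,
                     generations = 50, seed = 5, record_every = 10)
  sim0 <- run_simulation(cfg0)
  expect_true(sim0$extinct)
  expect_lte(sim0$final$generation, 2)
  # moderate lambda: lifespan deaths occur at roughly Nind/lambda per
  # generation early on (before contest replacement dominates)
  cfg1 <- sim_config(ns = 2000, delta = 0, lambda = 10, mu = 0,
                     generations = 200, seed = 6, record_every = 50,
                     initial_occupancy = 0.5)
  sim1 <- run_simulation(cfg1)
  expect_gt(sum(sim1$summary$deaths_lifespan), 0)
})

test_that("global extinction terminates the run gracefully", {
  # births (~ r * ns per generation) cannot keep up with 1-generation
  # lifespans, so the community must die out mid-run and be flagged
  cfg <- sim_config(ns = 50, delta = 0, lambda = 1, mu = 0,
                    generations = 500, seed = 13, record_every = 100,
                    mode = "neutral", r_neutral = 0.02,
                    initial_occupancy = 0.2)
  sim <- run_simulation(cfg)
  expect_true(sim$extinct)
  expect_lt(sim$final$generation, 500)
  expect_equal(sim$final$n_individuals, 0)
  expect_equal(sim$final$n_strains, 0)
})

test_that("a lone unconstrained strain fills the habitat monotonically", {
  cfg <- sim_config(ns = 400, delta = 0, lambda = Inf, mu = 0,
                    generations = 60, seed = 21, record_every = 10,
                    initial_occupancy = 0.05)
  sim <- run_simulation(cfg)
  # r = 1, no deaths: occupancy can never decrease and must saturate
  expect_true(all(diff(c(20, sim$summary$n_individuals)) >= 0))
  expect_equal(sim$summary$n_individuals[nrow(sim$summary)], 400)
})

test_that("neutral mode fixes replication and decides contests fairly", {
  cfg <- sim_config(ns = 300, delta = 0.7, lambda = Inf, mu = 5e-3, m = 0.02,
                    generations = 500, seed = 17, record_every = 100,
                    mode = "neutral", r_neutral = 0.5)
  sim <- run_simulation(cfg)
  st <- sim$final
  # uniform replication probability regardless of traits and delta
  expect_equal(st$replication_prob, rep(0.5, length(st$handles)))
  # traits still drift: mutants were established
  expect_gt(sum(sim$summary$mutations), 0)
  expect_gt(nrow(sim$lineage), 1)
})
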