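test_that("single-population TMRCA matches the coalescent expectation", {
  m <- one_pop_model(ne = 10000)
  set.seed(101)
  t2 <- replicate(3000, simulate_genealogy(m, c(A = 2))$tmrca)
  se <- sd(t2) / sqrt(length(t2))
  expect_lt(abs(mean(t2) - 20000), 3 * se)
})

test_that("lineages in different populations never coalesce before the split", {
  m <- two_pop_model(t_split = 5000)
  set.seed(7)
  t2 <- replicate(400, simulate_genealogy(
    m, c(A = 1, B = 1))$tmrca)
  expect_true(all(t2 >= 5000))
})

test_that("leaf TMRCA under the seven-canid model matches the epoch-integration oracle", {
  m <- canid_model("fig5a")
  path <- ne_path_of_leaf(m, "CRW")
  expected <- expected_t2_piecewise(path$breaks, path$ne)
  set.seed(202)
  t2 <- replicate(4000, simulate_genealogy(m, c(CRW = 2))$tmrca)
  se <- sd(t2) / sqrt(length(t2))
  expect_lt(abs(mean(t2) - expected), 3 * se)
})

test_that("dataset heterozygosity and divergence match closed forms", {
  # theta = 4 Ne mu within one population
  m1 <- one_pop_model(ne = 10000)
  ls1 <- simulate_dataset(m1, n_loci = 8000, locus_length = 1000,
                          mu = 1e-8, seed = 31, samples = c(A = 2))
  n_het <- sum(ls1$geno[, "A"] == 1L)
  expect_lt(abs(n_het / 8e6 - 4e-4), 3 * sqrt(n_het) / 8e6 + 1e-5)

  # E[dxy] = 2 mu (T + 2 Ne) between clean-split populations
  m2 <- two_pop_model(t_split = 5000, ne = 10000)
  ls2 <- simulate_dataset(m2, n_loci = 8000, mu = 1e-8, seed = 32,
                          samples = c(A = 2, B = 2))
  dxy <- pairwise_divergence(ls2$geno[, "A"], ls2$geno[, "B"],
                             called = 8e6, mode = "allpairs")
  expect_lt(abs(dxy - 5e-4), 3 * sqrt(5e-4 * 8e6) / 8e6 + 2e-5)

  # zero mutation rate gives zero variants
  expect_equal(nrow(simulate_dataset(m1, n_loci = 50, mu = 0, seed = 1,
                                     samples = c(A = 2))$geno), 0L)
})

test_that("simulation is deterministic under seed and subsets reproduce", {
  m <- two_pop_model()
  a <- simulate_dataset(m, n_loci = 100, mu = 1e-8, seed = 9,
                        samples = c(A = 2, B = 2))
  b <- simulate_dataset(m, n_loci = 100, mu = 1e-8, seed = 9,
                        samples = c(A = 2, B = 2))
  expect_identical(a, b)
  d <- simulate_dataset(m, n_loci = 100, mu = 1e-8, seed = 10,
                        samples = c(A = 2, B = 2))
  expect_false(identical(a$geno, d$geno))
  # loci are generated from per-locus streams: the first 50 loci of a
  # 100-locus run equal a 50-locus run with the same seed
  s <- simulate_dataset(m, n_loci = 50, mu = 1e-8, seed = 9,
                        samples = c(A = 2, B = 2))
  expect_identical(s$geno, a$geno[a$site$locus <= 50, ])
})

test_that("infinite-sites violations are refused with guidance", {
  m <- one_pop_model(ne = 10000)
  expect_error(simulate_dataset(m, n_loci = 2, locus_length = 10,
                                mu = 1e-2, seed = 1, samples = c(A = 2)),
               "infinite-sites")
})

test_that("trajectory genomes specialize the dataset simulator", {
  # constant trajectory reproduces the constant-Ne single population
  # stream for stream (same seed, same draws)
  tr_const <- piecewise_ne(numeric(0), 10000)
  g1 <- simulate_trajectory_genome(tr_const, n_loci = 200, mu = 1e-8,
                                   seed = 5, sample_name = "A")
  m1 <- one_pop_model(ne = 10000)
  g2 <- simulate_dataset(m1, n_loci = 200, mu = 1e-8, seed = 5,
                         samples = c(A = 2))
  expect_identical(g1$geno, g2$geno)

  # a bottleneck trajectory bounds heterozygosity between the two sizes
  tr_step <- piecewise_ne(2000, c(1000, 20000))
  g3 <- simulate_trajectory_genome(tr_step, n_loci = 4000, mu = 1e-8,
                                   seed = 6)
  het <- sum(g3$geno[, 1] == 1L) / (4000 * 1000)
  expect_gt(het, 4 * 1000 * 1e-8)
  expect_lt(het, 4 * 20000 * 1e-8)

  # two-epoch trajectory TMRCA matches the closed form
  tr2 <- piecewise_ne(3000, c(5000, 20000))
  expected <- expected_t2_piecewise(c(0, 3000), c(5000, 20000))
  m_tr <- demographic_model(
    data.frame(name = "A", parent = NA_character_, ne = 5000),
    setNames(numeric(0), character(0)), gen_time = 1,
    trajectories = list(A = tr2))
  set.seed(77)
  t2 <- replicate(3000, simulate_genealogy(m_tr, c(A = 2))$tmrca)
  se <- sd(t2) / sqrt(length(t2))
  expect_lt(abs(mean(t2) - expected), 3 * se)
})

test_that("depth tracks follow the Poisson copy-number model", {
  tr <- simulate_depth_track(rep(2L, 20000), 15, window = 1000, seed = 3)
  expect_lt(abs(mean(tr$depth) - 30), 3 * sqrt(30 / 20000))
  expect_equal(nrow(tr$windows), 20)

  tr0 <- simulate_depth_track(rep(0L, 500), 15, seed = 1)
  expect_true(all(tr0$depth == 0))

  tr29 <- simulate_depth_track(rep(29L, 10000), 15, seed = 2)
  expect_lt(abs(mean(tr29$depth) - 435), 3 * sqrt(435 / 10000))
  expect_error(simulate_depth_track(integer(0), 15, seed = 1),
               "non-empty")
})
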