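test_that("presence partition follows the homozygous 2/2 convention", {
  expect_equal(presence_partition(c(2, 2, 0, 0)), "BBAA")
  expect_equal(presence_partition(c(0, 2, 2, 0)), "ABBA")
  expect_equal(presence_partition(c(2, 0, 2, 0)), "BABA")
  # outgroup carrying the derived allele flips the reading
  expect_equal(presence_partition(c(0, 0, 2, 2)), "BBAA")
  expect_equal(presence_partition(c(2, 0, 0, 2)), "ABBA")
  # heterozygotes, monomorphic sites and 3/1 partitions do not qualify
  expect_equal(presence_partition(c(1, 0, 2, 0)), "other")
  expect_equal(presence_partition(c(0, 0, 0, 0)), "other")
  expect_equal(presence_partition(c(2, 2, 2, 0)), "other")
  expect_equal(presence_partition(c(NA, 2, 0, 0)), "other")
})

test_that("pattern counting tallies constructed sites and blocks correctly", {
  geno <- rbind(c(0, 2, 2, 0),   # ABBA
                c(2, 0, 2, 0),   # BABA
                c(2, 2, 0, 0),   # BBAA
                c(1, 1, 2, 0),   # heterozygous: strict-other
                c(0, 0, 0, 0))   # monomorphic
  colnames(geno) <- c("P1", "P2", "P3", "O")
  ls <- toy_locus_set(geno, loci = c(1L, 2L, 3L, 4L, 5L), n_loci = 5)
  tab <- count_patterns(quartet_spec("P1", "P2", "P3", "O"), ls,
                        block_size = 1)
  expect_equal(c(tab$n_abba, tab$n_baba, tab$n_bbaa), c(1, 1, 1))
  expect_equal(tab$freq, rep(1 / 3, 3))
  expect_equal(colSums(tab$blocks[, c("n_abba", "n_baba", "n_bbaa")]),
               c(n_abba = 1, n_baba = 1, n_bbaa = 1))
  # weighted mode gives the het site fractional ABBA/BABA weight
  expect_equal(tab$w_abba, 1 + 0.25)
  expect_equal(tab$w_baba, 1 + 0.25)

  empty <- toy_locus_set(matrix(0L, 2, 4,
                                dimnames = list(NULL,
                                                c("P1", "P2", "P3", "O"))))
  tab0 <- count_patterns(quartet_spec("P1", "P2", "P3", "O"), empty)
  expect_equal(c(tab0$n_abba, tab0$n_baba, tab0$n_bbaa), c(0, 0, 0))
})

test_that("D statistic formula, symmetry and error paths", {
  geno <- rbind(matrix(rep(c(0, 2, 2, 0), 20), ncol = 4, byrow = TRUE),
                matrix(rep(c(2, 0, 2, 0), 10), ncol = 4, byrow = TRUE))
  colnames(geno) <- c("P1", "P2", "P3", "O")
  ls <- toy_locus_set(geno, loci = rep(1:30, length.out = 30),
                      n_loci = 30)
  tab <- count_patterns(quartet_spec("P1", "P2", "P3", "O"), ls, 1)
  expect_equal(d_statistic(tab, "strict"), 1 / 3)
  expect_equal(d_statistic(tab, "weighted"), 1 / 3)
  # relabeling P1 <-> P2 swaps ABBA/BABA and negates D
  tab_sw <- count_patterns(quartet_spec("P2", "P1", "P3", "O"), ls, 1)
  expect_equal(tab_sw$n_abba, tab$n_baba)
  expect_equal(tab_sw$n_baba, tab$n_abba)
  expect_equal(d_statistic(tab_sw, "strict"), -1 / 3)

  mono <- toy_locus_set(matrix(0L, 1, 4,
                               dimnames = list(NULL,
                                               c("P1", "P2", "P3", "O"))))
  expect_error(d_statistic(count_patterns(
    quartet_spec("P1", "P2", "P3", "O"), mono)), "undefined")
})

test_that("block jackknife matches a brute-force oracle", {
  # 25 blocks with hand-set, unequal ABBA/BABA counts
  set.seed(42)
  abba <- rpois(25, 30); baba <- rpois(25, 24)
  rows <- list()
  for (b in 1:25) {
    if (abba[b]) rows[[length(rows) + 1]] <-
        cbind(matrix(rep(c(0, 2, 2, 0), abba[b]), ncol = 4, byrow = TRUE),
              b)
    if (baba[b]) rows[[length(rows) + 1]] <-
        cbind(matrix(rep(c(2, 0, 2, 0), baba[b]), ncol = 4, byrow = TRUE),
              b)
  }
  m <- do.call(rbind, rows)
  geno <- m[, 1:4]
  colnames(geno) <- c("P1", "P2", "P3", "O")
  ls <- toy_locus_set(geno, loci = m[, 5], n_loci = 25)
  tab <- count_patterns(quartet_spec("P1", "P2", "P3", "O"), ls,
                        block_size = 1)
  jz <- jackknife_z(tab, mode = "strict")
  oracle <- brute_jackknife(tab$blocks$n_abba, tab$blocks$n_baba)
  expect_equal(jz$D, oracle$D)
  expect_equal(jz$SE, oracle$SE)
  expect_equal(jz$Z, oracle$Z)

  # identical blocks: zero variance is an explicit error
  geno_id <- matrix(rep(c(0, 2, 2, 0), 25), ncol = 4, byrow = TRUE)
  colnames(geno_id) <- c("P1", "P2", "P3", "O")
  ls_id <- toy_locus_set(geno_id, loci = 1:25, n_loci = 25)
  tab_id <- count_patterns(quartet_spec("P1", "P2", "P3", "O"), ls_id, 1)
  expect_error(jackknife_z(tab_id, mode = "strict"), "variance")
  # too few blocks
  expect_error(jackknife_z(count_patterns(
    quartet_spec("P1", "P2", "P3", "O"), ls_id, block_size = 5),
    mode = "strict"), "blocks")
})

test_that("quartet enumeration covers both modes", {
  expect_length(enumerate_quartets(letters[1:6], "o"), 20)
  expect_length(enumerate_quartets(letters[1:3], "o"), 1)
  qs <- enumerate_quartets(c(dog_samples, wolf_samples), "GLJ",
                           mode = "dog_wolf_test", groups = canid_groups)
  expect_length(qs, 18)
  # P3 and the receiving pair always come from opposite groups
  for (q in qs) {
    g3 <- canid_groups[q$p3]
    expect_true(all(canid_groups[c(q$p1, q$p2)] != g3))
  }
  expect_error(enumerate_quartets(letters[1:4], "o",
                                  mode = "dog_wolf_test"), "labels")
})

test_that("model-fit score sums absolute frequency differences and flags cells", {
  obs <- data.frame(p1 = c("a", "a"), p2 = c("b", "b"),
                    p3 = c("c", "d"), outgroup = "o",
                    f_abba = c(0.2, 0.3), f_baba = c(0.3, 0.3),
                    f_bbaa = c(0.5, 0.4))
  expect_equal(model_fit_error(obs, obs)$score, 0)
  expect_equal(nrow(model_fit_error(obs, obs)$flags), 0)

  sim <- obs
  sim$f_abba[1] <- 0.21; sim$f_baba[1] <- 0.29
  fit <- model_fit_error(obs, sim)
  expect_equal(fit$score, 0.02)
  expect_equal(nrow(fit$flags), 0)      # both diffs at 1%, under 1.5%

  sim2 <- obs
  sim2$f_bbaa[2] <- 0.42
  fit2 <- model_fit_error(obs, sim2)
  expect_equal(fit2$score, 0.02, tolerance = 1e-12)
  expect_equal(fit2$flags$configuration, "BBAA")

  expect_error(model_fit_error(obs, obs[1, ]), "same quartets")
})

test_that("simulated quartets put the tree-concordant pattern first and gene flow skews D", {
  m <- canid_model("fig5a")
  ls <- simulate_dataset(m, n_loci = 1500, mu = 1e-8, seed = 13,
                         samples = c(BSJ = 2, DNG = 2, CRW = 2, GLJ = 2))
  tab <- count_patterns(quartet_spec("BSJ", "DNG", "CRW", "GLJ"), ls, 50)
  expect_gt(tab$n_bbaa, tab$n_abba)
  expect_gt(tab$n_bbaa, tab$n_baba)

  # strong CHW -> DNG band: ABBA excess for (BSJ, DNG, CHW | GLJ)
  mig <- canid_model("fig5a", migration = TRUE)
  mig$bands <- mig$bands[mig$bands$source == "CHW" &
                           mig$bands$target == "DNG", ]
  mig$bands$m_tot <- 0.5
  mig$bands$m <- mig$bands$m_tot / (mig$bands$t_hi - mig$bands$t_lo)
  ls_m <- simulate_dataset(mig, n_loci = 3000, mu = 1e-8, seed = 14,
                           samples = c(BSJ = 2, DNG = 2, CHW = 2,
                                       GLJ = 2))
  tab_m <- count_patterns(quartet_spec("BSJ", "DNG", "CHW", "GLJ"),
                          ls_m, 50)
  expect_gt(d_statistic(tab_m), 0)
})
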