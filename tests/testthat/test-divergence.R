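test_that("the two divergence estimators treat heterozygotes as specified", {
  # AA vs AA; AA vs AT; AA vs TT  (dosages 0/0, 0/1, 0/2)
  expect_equal(pairwise_divergence(0L, 0L, 1, "conservative"), 0)
  expect_equal(pairwise_divergence(0L, 0L, 1, "allpairs"), 0)
  expect_equal(pairwise_divergence(0L, 1L, 1, "conservative"), 0)
  expect_equal(pairwise_divergence(0L, 1L, 1, "allpairs"), 0.5)
  expect_equal(pairwise_divergence(0L, 2L, 1, "conservative"), 1)
  expect_equal(pairwise_divergence(0L, 2L, 1, "allpairs"), 1)
  # pointwise dominance: allpairs >= conservative on random dosages
  set.seed(1)
  a <- sample(0:2, 500, TRUE); b <- sample(0:2, 500, TRUE)
  expect_gte(pairwise_divergence(a, b, 500, "allpairs"),
             pairwise_divergence(a, b, 500, "conservative"))
  expect_error(pairwise_divergence(1L, 1L, 0), "called")
})

test_that("distance matrices match hand-computed values and window partials sum", {
  geno <- rbind(c(0, 0, 2, 2),
                c(0, 1, 1, 2),
                c(0, 2, 0, 2),
                c(0, 0, 0, 1),
                c(2, 2, 2, 2))
  colnames(geno) <- c("s1", "s2", "s3", "s4")
  ls <- toy_locus_set(geno, loci = c(1L, 1L, 2L, 2L, 2L), n_loci = 2,
                      locus_length = 10L)
  dm <- distance_matrix(ls, mode = "allpairs", window_loci = 1)
  # by hand: mismatch fractions per site, 20 called sites per pair
  expect_equal(dm$d["s1", "s2"], (0 + 0.5 + 1 + 0 + 0) / 20)
  expect_equal(dm$d["s1", "s4"], (1 + 1 + 1 + 0.5 + 0) / 20)
  expect_equal(dm$d["s2", "s3"], (1 + 0.5 + 1 + 0 + 0) / 20)
  expect_true(isSymmetric(dm$d))
  expect_equal(colSums(dm$window_mismatch)["s1|s2"],
               c("s1|s2" = 1.5))
  expect_equal(colSums(dm$window_called), rep(20, 6),
               ignore_attr = TRUE)

  # identical samples give a zero matrix
  g0 <- matrix(0L, 3, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_true(all(distance_matrix(toy_locus_set(g0))$d == 0))
})

test_that("neighbor joining recovers additive trees exactly", {
  # 4-taxon additive matrix from known branch lengths:
  # ((A:2,B:3):1,(C:4,D:5):1)
  d <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  d["A", "B"] <- d["B", "A"] <- 5
  d["A", "C"] <- d["C", "A"] <- 8
  d["A", "D"] <- d["D", "A"] <- 9
  d["B", "C"] <- d["C", "B"] <- 9
  d["B", "D"] <- d["D", "B"] <- 10
  d["C", "D"] <- d["D", "C"] <- 9
  tr <- nj_tree(d)
  truth <- ape::read.tree(text = "((A:2,B:3):1,(C:4,D:5):1);")
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(truth)), 0,
               ignore_attr = TRUE)
  # branch lengths recovered (sum preserved and per-pair path lengths)
  expect_equal(sum(tr$edge.length), sum(truth$edge.length))
  expect_equal(as.matrix(ape::cophenetic.phylo(tr))[rownames(d),
                                                    colnames(d)], d)
  # 3 taxa: unique star resolution with exact lengths
  d3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr3 <- nj_tree(d3)
  expect_equal(sort(tr3$edge.length), c(0.5, 1.5, 2.5))
  # determinism under ties
  expect_identical(ape::write.tree(nj_tree(d)),
                   ape::write.tree(nj_tree(d)))
  d[1, 2] <- NA; d[2, 1] <- NA
  expect_error(nj_tree(d), "non-finite")
})

test_that("window bootstrap is reproducible, label-invariant and handles one window", {
  pops <- data.frame(name = c("A", "B", "C", "AB", "R"),
                     parent = c("AB", "AB", "R", "R", NA),
                     ne = c(5000, 5000, 5000, 5000, 5000))
  m3 <- demographic_model(pops, c(AB = 20000, R = 100000), gen_time = 1)
  ls <- simulate_dataset(m3, n_loci = 300, mu = 1e-8, seed = 21,
                         samples = c(A = 2, B = 2, C = 2))
  dm <- distance_matrix(ls, mode = "allpairs", window_loci = 10)
  b1 <- window_bootstrap_support(dm, n_reps = 50, seed = 4,
                                 outgroup = "C")
  b2 <- window_bootstrap_support(dm, n_reps = 50, seed = 4,
                                 outgroup = "C")
  expect_identical(ape::write.tree(b1), ape::write.tree(b2))
  expect_true(all(as.numeric(b1$node.label) >= 0 &
                    as.numeric(b1$node.label) <= 100))
  # single window: warning and 100% everywhere
  dm1 <- distance_matrix(ls, mode = "allpairs", window_loci = 300)
  expect_warning(bs <- window_bootstrap_support(dm1, n_reps = 20,
                                                seed = 1,
                                                outgroup = "C"),
                 "single window")
  expect_true(all(as.numeric(bs$node.label) == 100))
  # window order invariance
  perm <- sample(nrow(dm$window_mismatch))
  dm_p <- dm
  dm_p$window_mismatch <- dm$window_mismatch[perm, ]
  dm_p$window_called <- dm$window_called[perm, ]
  bp <- window_bootstrap_support(dm_p, n_reps = 50, seed = 4,
                                 outgroup = "C")
  expect_identical(b1$node.label, bp$node.label)
})

test_that("split-time moment estimator converts net divergence to years", {
  expect_equal(split_time_moment_estimator(4e-4, 4e-4, 4e-4, 1e-8)$years,
               0)
  out <- split_time_moment_estimator(5e-4, 4e-4, 4e-4, 1e-8, 3)
  expect_equal(out$years, 15000)
  expect_false(out$clamped)
  cl <- split_time_moment_estimator(1e-4, 4e-4, 4e-4, 1e-8, 3)
  expect_equal(cl$years, 0)
  expect_true(cl$clamped)
  expect_error(split_time_moment_estimator(1e-4, 0, 0, 0), "mu")
})

test_that("PHYLIP square matrices round-trip", {
  m <- matrix(c(0, 0.1, 0.2, 0.1, 0, 0.3, 0.2, 0.3, 0), 3,
              dimnames = list(c("alpha", "beta", "gamma"),
                              c("alpha", "beta", "gamma")))
  path <- tempfile(fileext = ".phy")
  write_phylip(m, path)
  expect_equal(read_phylip(path), m, tolerance = 1e-8)
})
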