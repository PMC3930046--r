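test_that("allele frequencies are the non-missing B-allele dose fraction", {
  m <- genotype_matrix(matrix(c(1L, 2L), 2, 1), c("a", "b"),
                       c("p1", "p1"), "L1")
  f <- allele_frequencies(m)
  expect_equal(unname(f$freq[1, 1]), 0.75)
  expect_equal(unname(f$n_obs[1, 1]), 2L)

  m0 <- genotype_matrix(matrix(0L, 3, 2), paste0("i", 1:3), rep("p", 3),
                        c("L1", "L2"))
  expect_equal(unname(allele_frequencies(m0)$freq), matrix(0, 1, 2))

  # brute-force per-individual tally on random matrices
  for (seed in 1:10) {
    m <- random_matrix(seed, missing_rate = 0.2)
    f <- allele_frequencies(m)
    for (p in f$pops) for (j in seq_along(m$loci)) {
      g <- m$calls[m$populations == p, j]
      g <- g[!is.na(g)]
      want <- if (length(g)) sum(g) / (2 * length(g)) else NA_real_
      expect_equal(unname(f$freq[p, j]), want)
    }
  }
})

test_that("Latter distance matches hand-evaluated cases exactly", {
  f <- pop_freqs(rbind(c(0, 1, 0.5), c(0, 1, 0.5)),
                 matrix(Inf, 2, 3), c("x", "y"), paste0("L", 1:3))
  expect_equal(latter_fst_distance(f, "x", "y"), 0)

  # one locus, x fixed B vs y fixed A: D = 1
  f1 <- pop_freqs(rbind(1, 0), matrix(Inf, 2, 1), c("x", "y"), "L1")
  expect_equal(latter_fst_distance(f1, "x", "y"), 1, tolerance = 1e-12)

  # one locus, x fixed vs y = 0.5: D = 0.25 / 0.5 = 0.5
  f2 <- pop_freqs(rbind(1, 0.5), matrix(Inf, 2, 1), c("x", "y"), "L1")
  expect_equal(latter_fst_distance(f2, "x", "y"), 0.5, tolerance = 1e-12)

  # identically fixed everywhere: denominator zero -> 0 by convention
  f3 <- pop_freqs(rbind(c(1, 0), c(1, 0)), matrix(Inf, 2, 2),
                  c("x", "y"), c("L1", "L2"))
  expect_equal(latter_fst_distance(f3, "x", "y"), 0)

  # loci with absent frequencies are excluded from both sums
  f4 <- pop_freqs(rbind(c(1, NA), c(0.5, 0.2)), matrix(Inf, 2, 2),
                  c("x", "y"), c("L1", "L2"))
  expect_equal(latter_fst_distance(f4, "x", "y"), 0.5)
})

test_that("Latter distance matrix is symmetric, non-negative, zero iff equal", {
  for (seed in 1:10) {
    m <- random_matrix(seed, n_pops = 4, max_ind = 8, max_loci = 10)
    f <- allele_frequencies(m)
    D <- latter_fst_matrix(f)
    expect_equal(D, t(D))
    expect_true(all(D >= 0))
    expect_true(all(diag(D) == 0))
  }
  fdup <- pop_freqs(rbind(c(0.3, 0.7), c(0.3, 0.7)), matrix(Inf, 2, 2),
                    c("x", "y"), c("L1", "L2"))
  expect_equal(latter_fst_distance(fdup, "x", "y"), 0)
})

test_that("Weir-Cockerham theta hits its analytic anchors", {
  # maximal differentiation: alternative fixation
  m <- fixed_alt_matrix(20, 5)
  expect_equal(wc_fst(m)$multilocus, 1, tolerance = 0.01)

  # null: one panmictic pool split arbitrarily in two
  cfg <- pop_sim_config(n_pops = 2, pop_sizes = c(500L, 500L),
                        n_loci = 200L, divergence = 0)
  m0 <- sim_genotypes(sim_population_frequencies(cfg, seed = 2),
                      cfg$pop_sizes, seed = 3)
  th <- wc_fst(m0)
  per <- th$per_locus[!is.na(th$per_locus)]
  se <- stats::sd(per) / sqrt(length(per))
  expect_lt(abs(th$multilocus), 3 * se)

  # monomorphic locus excluded, not poisoning the multilocus ratio
  mm <- genotype_matrix(cbind(c(0L, 0L, 2L, 2L), rep(0L, 4)),
                        paste0("i", 1:4), rep(c("A", "B"), each = 2),
                        c("poly", "mono"))
  r <- wc_fst(mm)
  expect_true(is.na(r$per_locus["mono"]))
  expect_equal(unname(r$per_locus["poly"]), r$multilocus)
})

test_that("Weir-Cockerham theta recovers the simulated drift parameter", {
  cfg <- pop_sim_config(n_pops = 2, pop_sizes = c(100L, 100L),
                        n_loci = 2000L, divergence = 0.2)
  m <- sim_genotypes(sim_population_frequencies(cfg, seed = 11),
                     cfg$pop_sizes, seed = 12)
  expect_lt(abs(wc_fst(m)$multilocus - 0.2), 0.03)
})

test_that("UPGMA produces the documented heights and tie-breaks", {
  d <- matrix(c(0, 0.4, 0.4, 0), 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  tr <- upgma(d)
  expect_equal(write_newick(tr), "(A:0.2,B:0.2);")
  expect_equal(unname(tr$heights["A|B"]), 0.2)

  # all distances tied: lexicographically smallest pair merges first
  d3 <- matrix(1, 3, 3); diag(d3) <- 0
  dimnames(d3) <- list(c("C", "B", "A"), c("C", "B", "A"))
  expect_match(write_newick(upgma(d3)), "\\(A:0.5,B:0.5\\)")

  expect_error(upgma(matrix(c(0, 1, 2, 0), 2,
                            dimnames = list(c("A", "B"), c("A", "B")))),
               "symmetric")
})

test_that("UPGMA agrees with average-linkage hclust and is ultrametric", {
  for (trial in 1:100) {
    withr::with_seed(1000 + trial, {
      n <- sample(3:5, 1)
      d <- matrix(0, n, n)
      d[upper.tri(d)] <- stats::runif(n * (n - 1) / 2, 0.05, 1)
      d <- d + t(d)
      dimnames(d) <- list(LETTERS[1:n], LETTERS[1:n])
    })
    tr <- upgma(d)
    co <- tree_cophenetic(tr)
    ch <- as.matrix(stats::cophenetic(stats::hclust(stats::as.dist(d),
                                                    method = "average")))
    expect_lt(max(abs(co[rownames(ch), colnames(ch)] - ch)), 1e-8)
    # ultrametric: every leaf equidistant from the root
    depths <- ape::node.depth.edgelength(tr$phylo)[
      seq_along(tr$phylo$tip.label)]
    expect_lt(diff(range(depths)), 1e-12)
  }
})

test_that("locus bootstrap supports behave and are reproducible", {
  m <- sim_study_matrix(pop_sim_config(), seed = 5)
  b1 <- bootstrap_tree(m, n_reps = 1, seed = 7)
  expect_true(all(b1$supports %in% c(0L, 100L)))

  b2 <- bootstrap_tree(m, n_reps = 25, seed = 8)
  b3 <- bootstrap_tree(m, n_reps = 25, seed = 8)
  expect_identical(b2$supports, b3$supports)
  expect_true(all(b2$supports >= 0 & b2$supports <= 100))
})
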