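test_that("assignment log-likelihood matches hand-multiplied HWE values", {
  # three loci, two populations with printed frequencies
  f <- pop_freqs(rbind(c(0.2, 0.5, 0.9), c(0.7, 0.1, 0.4)),
                 matrix(10L, 2, 3), c("p1", "p2"), paste0("L", 1:3))
  g <- c(L1 = 0L, L2 = 1L, L3 = 2L)
  ll <- assignment_loglik(g, f)
  hand1 <- log(0.8^2) + log(2 * 0.5 * 0.5) + log(0.9^2)
  hand2 <- log(0.3^2) + log(2 * 0.1 * 0.9) + log(0.4^2)
  expect_equal(unname(ll["p1"]), hand1, tolerance = 1e-12)
  expect_equal(unname(ll["p2"]), hand2, tolerance = 1e-12)

  # fixed population, matching homozygote: probability ~1 after correction
  ffix <- pop_freqs(matrix(1, 1, 1), matrix(20L, 1, 1), "p1", "L1")
  llf <- assignment_loglik(c(L1 = 2L), ffix)
  expect_lt(abs(llf[["p1"]]), 0.1)
  expect_gt(llf[["p1"]], 2 * log(1 - 1 / 41) - 1e-12)

  # identical frequencies -> exact tie
  ftie <- pop_freqs(rbind(c(0.3, 0.6), c(0.3, 0.6)), matrix(5L, 2, 2),
                    c("p1", "p2"), c("L1", "L2"))
  lt <- assignment_loglik(c(L1 = 1L, L2 = 0L), ftie)
  expect_equal(unname(lt["p1"]), unname(lt["p2"]))

  expect_error(assignment_loglik(g, f, loci = character(0)), "non-empty")
  # missing genotypes are skipped
  llna <- assignment_loglik(c(L1 = 0L, L2 = NA, L3 = NA), f)
  expect_equal(unname(llna["p1"]), log(0.8^2), tolerance = 1e-12)
})

test_that("leave-one-out is perfect under alternative fixation, errors on n=1", {
  m <- fixed_alt_matrix(10, 3)
  r <- leave_one_out_accuracy(m)
  expect_equal(r$overall_accuracy, 1)
  expect_equal(unname(r$per_pop_accuracy), c(1, 1))
  expect_equal(sum(r$confusion), 20)

  bad <- genotype_matrix(matrix(c(0L, 2L, 1L), 3, 1), paste0("i", 1:3),
                         c("big", "big", "lonely"), "L1")
  expect_error(leave_one_out_accuracy(bad), "lonely")
})

test_that("duplicated-population null gives chance-level accuracy", {
  # one panmictic sample under two labels: expect ~50% (ties incorrect)
  cfg <- pop_sim_config(n_pops = 2, pop_sizes = c(40L, 40L),
                        n_loci = 60L, divergence = 0)
  m <- sim_genotypes(sim_population_frequencies(cfg, seed = 21),
                     cfg$pop_sizes, seed = 22)
  r <- leave_one_out_accuracy(m)
  # binomial tolerance: 3 * sqrt(.25/80) ~ 0.17
  expect_lt(abs(r$overall_accuracy - 0.5), 0.17)
})

test_that("leave-one-out accuracy is invariant to row and locus order", {
  m <- sim_study_matrix(pop_sim_config(n_loci = 40L), seed = 30)
  r <- leave_one_out_accuracy(m)
  perm_i <- withr::with_seed(1, sample(length(m$individuals)))
  perm_l <- withr::with_seed(2, sample(length(m$loci)))
  m2 <- genotype_matrix(m$calls[perm_i, perm_l],
                        m$individuals[perm_i], m$populations[perm_i],
                        m$loci[perm_l])
  r2 <- leave_one_out_accuracy(m2)
  expect_equal(r2$overall_accuracy, r$overall_accuracy)
  expect_equal(r2$per_pop_accuracy[sort(names(r$per_pop_accuracy))],
               r$per_pop_accuracy[sort(names(r$per_pop_accuracy))])
})

test_that("a fully diagnostic locus dominates every resampled ranking", {
  withr::with_seed(50, {
    n <- 30L
    calls <- cbind(rep(c(0L, 2L), each = n),              # diagnostic
                   matrix(sample(0:2, 2 * n * 10, TRUE,
                                 prob = c(.25, .5, .25)), 2 * n, 10))
  })
  m <- genotype_matrix(calls, sprintf("i%02d", 1:(2 * 30)),
                       rep(c("A", "B"), each = 30),
                       c("diag", sprintf("bg%02d", 1:10)))
  rk <- rank_loci(m, resample_sizes = c(40L, 40L), top_k = 5L, seed = 3)
  for (o in rk$per_dataset) expect_equal(o[1], "diag")
  expect_true("diag" %in% rk$consensus)

  rk2 <- rank_loci(m, resample_sizes = c(40L, 40L), top_k = 5L, seed = 3)
  expect_identical(rk$per_dataset, rk2$per_dataset)
  expect_identical(rk$scores, rk2$scores)
})

test_that("planted divergent loci are recovered by the consensus ranking", {
  f <- planted_freqs(n_pops = 4, n_div = 10, n_bg = 113, seed = 99)
  m <- sim_genotypes(f, rep(25L, 4), seed = 100)
  rk <- rank_loci(m, resample_sizes = c(100L, 100L, 100L, 500L),
                  top_k = 12L, seed = 101)
  expect_gt(length(rk$consensus), 0)
  frac_true <- mean(grepl("^DIV", rk$consensus))
  expect_gte(frac_true, 0.95)
})

test_that("select_min_panel returns minimal prefixes and flags failure", {
  m <- fixed_alt_matrix(10, 4)
  sel <- select_min_panel(m, m$loci, target_accuracy = 1)
  expect_equal(length(sel$loci), 1L)
  expect_true(sel$reached)
  expect_equal(sel$accuracy, 1)

  # panmictic matrix cannot reach 99%
  cfg <- pop_sim_config(n_pops = 2, pop_sizes = c(20L, 20L),
                        n_loci = 20L, divergence = 0)
  m0 <- sim_genotypes(sim_population_frequencies(cfg, seed = 61),
                      cfg$pop_sizes, seed = 62)
  sel0 <- select_min_panel(m0, m0$loci, target_accuracy = 0.99)
  expect_false(sel0$reached)
  expect_equal(sel0$loci, m0$loci)
})

test_that("accuracy is non-decreasing in panel size on planted truth", {
  f <- planted_freqs(n_pops = 3, n_div = 6, n_bg = 30, seed = 70)
  m <- sim_genotypes(f, rep(20L, 3), seed = 71)
  ordered <- c(sprintf("DIV%02d", 1:6), sprintf("BG%03d", 1:4))
  accs <- vapply(c(1L, 3L, 6L), function(k)
    leave_one_out_accuracy(m, ordered[seq_len(k)])$overall_accuracy,
    numeric(1))
  expect_true(all(diff(accs) >= -0.05))
  expect_gte(accs[3], accs[1])
})
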