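test_that("inside recursion reproduces hand-computable partition functions", {
  expect_equal(compute_inside(toy_model, "AAAAAAAA")$Ztotal, 1)
  # GCAAAAGC has 4 structures: empty, two lone pairs (E = +2 each), and the
  # stacked helix (E = -2 + 2 = 0)
  expect_equal(compute_inside(toy_model, "GCAAAAGC")$Ztotal,
               2 + 2 * exp(-2 / 0.6), tolerance = 1e-12)
  tb <- compute_inside(toy_model, "GCAAAAGC")
  expect_true(all(diag(tb$Z) == 1))
})

test_that("zeroed energies turn the partition function into a count", {
  for (s in rand_seqs(5, 10, 18, seed = 21)) {
    expect_equal(compute_inside(zero_model, s)$Ztotal,
                 count_structures(toy_model, s, "all"))
  }
})

test_that("inside Z matches the enumeration oracle", {
  for (s in rand_seqs(8, 10, 20, seed = 22)) {
    expect_equal(compute_inside(toy_model, s)$Ztotal,
                 brute_partition_function(toy_model, s, "all"),
                 tolerance = 1e-10)
    expect_equal(compute_inside(turner_model, s)$Ztotal,
                 brute_partition_function(turner_model, s, "all"),
                 tolerance = 1e-8)
  }
})

test_that("pair probabilities are exact and satisfy the sum rule", {
  pp <- pair_probabilities(toy_model, "GCAAAAGC")
  expect_equal(pp$p[1, 8], 0.5, tolerance = 1e-12)
  expect_equal(pp$p[2, 7], 0.5, tolerance = 1e-12)
  pa <- pair_probabilities(toy_model, "AAAAAAAA")
  expect_true(all(pa$p == 0))
  expect_true(all(pa$q == 1))
  for (model in list(toy_model, turner_model)) {
    for (s in rand_seqs(4, 12, 25, seed = 23)) {
      pp <- pair_probabilities(model, s)
      expect_true(all(abs(rowSums(pp$p) + pp$q - 1) < 1e-9))
      expect_equal(pp$p, t(pp$p))
    }
  }
})

test_that("pair probabilities agree with brute-force marginal sums", {
  for (model in list(toy_model, turner_model)) {
    for (s in rand_seqs(3, 10, 16, seed = 24)) {
      b <- brute_ensemble(model, s, collect_all = TRUE)
      ex <- exact_pair_frequencies(b$all_structures, b$all_energies, model)
      pp <- pair_probabilities(model, s)
      expect_equal(pp$p, ex$p, tolerance = 1e-9)
      expect_equal(pp$q, ex$q, tolerance = 1e-9)
    }
  }
})

test_that("Boltzmann sampling over all structures is correct and reproducible", {
  s5 <- sample_all(toy_model, "AAAAAAAA", k = 5, seed = 1)
  expect_equal(s5$structure, rep("........", 5))
  a <- sample_all(toy_model, "GCAAAAGC", k = 200, seed = 99)
  b <- sample_all(toy_model, "GCAAAAGC", k = 200, seed = 99)
  expect_identical(a, b)
  # exact probability of the full helix is 1/Z
  smp <- sample_all(toy_model, "GCAAAAGC", k = 10000, seed = 1)
  expect_equal(mean(smp$structure == "((....))"),
               1 / (2 + 2 * exp(-2 / 0.6)), tolerance = 0.035)
})

test_that("sampled frequencies converge to the exact distribution", {
  for (s in rand_seqs(2, 12, 18, seed = 25)) {
    b <- brute_ensemble(turner_model, s, collect_all = TRUE)
    pr <- exp(-b$all_energies / turner_model$RT)
    pr <- pr / sum(pr)
    smp <- sample_all(turner_model, s, k = 10000, seed = 4)
    emp <- table(factor(smp$structure, levels = b$all_structures)) / 10000
    tv <- 0.5 * sum(abs(as.numeric(emp) - pr))
    expect_lt(tv, 0.05)
  }
})
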