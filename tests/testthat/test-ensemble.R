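test_that("empirical frequencies count structures correctly", {
  f <- empirical_pair_frequencies(c("........", "((....))"))
  expect_equal(f$p[1, 8], 0.5)
  expect_equal(f$p[2, 7], 0.5)
  expect_equal(f$q[3], 1.0)
  expect_equal(f$q[1], 0.5)
  f2 <- empirical_pair_frequencies(rep("((....))", 7))
  expect_true(all(abs(f2$p) < 1e-12 | abs(f2$p - 1) < 1e-12))
  expect_true(all(abs(rowSums(f$p) + f$q - 1) < 1e-12))
  # sampled locally optimal frequencies approach the exact ones
  sm <- sample_locopt(toy_model, "GCAAAAGC", k = 10000, seed = 2)
  f3 <- empirical_pair_frequencies(sm)
  expect_equal(f3$p[1, 8], 0.5, tolerance = 0.03)
})

test_that("pseudo-entropy matches its closed form", {
  p1 <- matrix(0, 8, 8); p1[1, 8] <- p1[8, 1] <- 1
  expect_equal(pseudo_entropy(p1), 0)
  p2 <- matrix(0, 8, 8)
  p2[1, 8] <- p2[8, 1] <- 0.5
  p2[2, 7] <- p2[7, 2] <- 0.5
  expect_equal(pseudo_entropy(p2), log(2))
  p3 <- matrix(0, 8, 8); p3[1, 8] <- p3[8, 1] <- 0.5
  expect_equal(pseudo_entropy(p3), 0.5 * log(2), tolerance = 1e-12)
})

test_that("average positional entropy matches its closed form", {
  # point mass
  p1 <- matrix(0, 8, 8); p1[1, 8] <- p1[8, 1] <- 1
  q1 <- c(0, rep(1, 6), 0)
  expect_equal(average_entropy(p1, q1), 0)
  # four positions with a fair coin each
  p2 <- matrix(0, 8, 8)
  p2[1, 8] <- p2[8, 1] <- p2[2, 7] <- p2[7, 2] <- 0.5
  q2 <- c(0.5, 0.5, 1, 1, 1, 1, 0.5, 0.5)
  expect_equal(average_entropy(p2, q2), 4 * log(2) / 8)
  expect_error(average_entropy(p2, rep(1, 8)), "sum rule")
})

test_that("Morgan-Higgs diversity matches its closed form", {
  p1 <- matrix(0, 8, 8); p1[1, 8] <- p1[8, 1] <- 1
  expect_equal(morgan_higgs_diversity(p1, c(0, rep(1, 6), 0)), 0)
  p2 <- matrix(0, 8, 8)
  p2[1, 8] <- p2[8, 1] <- p2[2, 7] <- p2[7, 2] <- 0.5
  expect_equal(morgan_higgs_diversity(p2, c(0.5, 0.5, 1, 1, 1, 1, 0.5, 0.5)),
               2.0)
  p3 <- matrix(0, 8, 8); p3[1, 8] <- p3[8, 1] <- 0.5
  expect_equal(morgan_higgs_diversity(p3, c(0.5, rep(1, 6), 0.5)), 1.0)
})

test_that("Vienna diversity equals the expected base-pair distance", {
  p1 <- matrix(0, 8, 8); p1[1, 8] <- p1[8, 1] <- 1
  expect_equal(vienna_diversity(p1), 0)
  p2 <- matrix(0, 8, 8)
  p2[1, 8] <- p2[8, 1] <- p2[2, 7] <- p2[7, 2] <- 0.5
  expect_equal(vienna_diversity(p2), 1.0)
  # closed form equals the explicit double sum over the exact ensemble
  for (s in rand_seqs(3, 10, 15, seed = 51)) {
    b <- brute_ensemble(toy_model, s, collect_all = TRUE)
    pr <- exp(-b$all_energies / toy_model$RT)
    pr <- pr / sum(pr)
    f <- exact_pair_frequencies(b$all_structures, b$all_energies, toy_model)
    sts <- lapply(b$all_structures, parse_dot_bracket)
    dsum <- 0
    for (u in seq_along(sts)) for (v in seq_along(sts))
      dsum <- dsum + pr[u] * pr[v] * base_pair_distance(sts[[u]], sts[[v]])
    expect_equal(vienna_diversity(f$p), dsum, tolerance = 1e-9)
  }
})

test_that("coverage statistics follow their definition", {
  # two distinct structures of energy 0, reference Z = 4 -> coverage 1/2
  smp <- data.frame(structure = c("........", "........", "((....))"),
                    energy = c(0, 0, 0))
  cv <- coverage_statistics(smp, Zref = 4, toy_model, "GCAAAAGC")
  expect_equal(cv$n_distinct, 2)
  expect_equal(cv$coverage, 0.5)
  # both locally optimal structures of the micro-example appear w.h.p.
  sm <- sample_locopt(toy_model, "GCAAAAGC", k = 1000, seed = 3)
  cv2 <- coverage_statistics(sm, Zref = 2, toy_model, "GCAAAAGC")
  expect_equal(cv2$n_distinct, 2)
  expect_equal(cv2$coverage, 1.0, tolerance = 1e-12)
  expect_lte(cv2$coverage, 1)
})

test_that("locally optimal ensembles of designed hairpins are less diverse", {
  rows <- lapply(designed_hairpins, function(s)
    diversity_report(toy_model, s, k = 400, seed = 17))
  lo <- do.call(rbind, lapply(rows, function(r) r[r$ensemble == "locopt", -1]))
  al <- do.call(rbind, lapply(rows, function(r) r[r$ensemble == "all", -1]))
  for (m in c("Q", "avg_entropy", "d_mh", "d_v")) {
    expect_lte(mean(lo[[m]]), mean(al[[m]]))
  }
})
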