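test_that("entrywise minima combine the two probability sets", {
  pm <- matrix(0, 8, 8); pm[1, 8] <- pm[8, 1] <- 0.9
  plo <- matrix(0, 8, 8); plo[1, 8] <- plo[8, 1] <- 0.4
  qm <- rep(0.5, 8); qlo <- rep(0.3, 8)
  mn <- combine_min(pm, qm, plo, qlo)
  expect_equal(mn$p[1, 8], 0.4)
  expect_equal(mn$q, rep(0.3, 8))
  idm <- combine_min(pm, qm, pm, qm)
  expect_identical(idm$p, pm)
  expect_error(combine_min(pm, qm, plo[1:4, 1:4], qlo), "dimension")
  # the sum rule may fail after combining; that is flagged by contract, not
  # an error
  expect_lt(max(rowSums(mn$p) + mn$q), 1)
})

test_that("MEA folding maximizes the expected-accuracy score", {
  # degenerate point mass on (1,8)
  p <- matrix(0, 8, 8); p[1, 8] <- p[8, 1] <- 1
  q <- c(0, rep(1, 6), 0)
  out <- mea_fold(p, q, gamma = 1)
  expect_equal(format_dot_bracket(out$structure), "(......)")
  expect_equal(out$score, 2 + 6)
  # exact toy probabilities with gamma = 2: the full helix wins
  pp <- pair_probabilities(toy_model, "GCAAAAGC")
  out2 <- mea_fold(pp$p, pp$q, gamma = 2)
  expect_equal(format_dot_bracket(out2$structure), "((....))")
  expect_equal(out2$score, 2 * 2 * (0.5 + 0.5) + 4)
})

test_that("MEA DP equals the brute-force maximum over all structures", {
  set.seed(61)
  for (rep in 1:12) {
    n <- sample(10:18, 1)
    s <- paste(sample(c("A", "C", "G", "U"), n, TRUE), collapse = "")
    pp <- pair_probabilities(turner_model, s)
    sts <- enumerate_structures(s)
    for (gamma in c(0.5, 1, 2)) {
      brute <- max(vapply(sts, function(db) {
        st <- parse_dot_bracket(db)
        paired <- if (nrow(st$pairs) > 0) sum(pp$p[st$pairs]) else 0
        unpaired <- sum(pp$q[setdiff(seq_len(n), c(st$pairs))])
        2 * gamma * paired + unpaired
      }, numeric(1)))
      out <- mea_fold(pp$p, pp$q, gamma = gamma)
      expect_equal(out$score, brute, tolerance = 1e-9)
    }
  }
})

test_that("MEA output is a valid structure even for MIN-combined input", {
  set.seed(62)
  s <- rand_seqs(1, 25, 25, seed = 62)
  pp <- pair_probabilities(turner_model, s)
  fl <- empirical_pair_frequencies(sample_locopt(turner_model, s, k = 500,
                                                 seed = 1))
  mn <- combine_min(pp$p, pp$q, fl$p, fl$q)
  out <- mea_fold(mn$p, mn$q, gamma = 2)
  expect_s3_class(out$structure, "rna_structure")  # constructor validates
  # paired score component is monotone non-decreasing in gamma
  scores <- vapply(c(0.5, 1, 2, 4), function(g) {
    st <- mea_fold(mn$p, mn$q, gamma = g)$structure
    if (nrow(st$pairs) > 0) sum(mn$p[st$pairs]) else 0
  }, numeric(1))
  expect_true(all(diff(scores) >= -1e-12))
})

test_that("sensitivity and PPV use exact pair matching", {
  pred <- secondary_structure(rbind(c(1, 8), c(2, 7)), 10)
  ref <- secondary_structure(rbind(c(1, 8), c(3, 7)), 10)
  sp <- sensitivity_ppv(pred, ref)
  expect_equal(sp$sensitivity, 0.5)
  expect_equal(sp$ppv, 0.5)
  sp2 <- sensitivity_ppv(ref, ref)
  expect_equal(unlist(sp2), c(sensitivity = 1, ppv = 1))
  sp3 <- sensitivity_ppv(secondary_structure(NULL, 10), ref)
  expect_equal(sp3$sensitivity, 0)
  expect_true(is.na(sp3$ppv))
})
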