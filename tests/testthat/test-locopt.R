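test_that("hairpin addition flags catch energy-lowering insertions", {
  flags <- precompute_delta_flags(toy_model, "GCAAAAGC")
  # inserting (2,7) into hairpin (1,8) gains a -2 stack for a +2 hairpin:
  # dE = (-2 + 2) - 2 = -2 < 0
  expect_false(flags$hp_ok[1, 8])
  # hairpin (2,7) encloses only A's: nothing insertable
  expect_true(flags$hp_ok[2, 7])
  flags2 <- precompute_delta_flags(toy_model, "GCAAAAGC")
  expect_equal(flags$hp_ok, flags2$hp_ok)
})

test_that("merge delta follows the internal-loop arithmetic", {
  # two stacks: removing the middle pair merges them into a +1 interior
  # loop: dE = 1 - (-2 - 2) = +5 >= 0
  s <- "GGGCAAAAGCCC"
  expect_equal(delta_merge_internal(toy_model, s, 1, 12, 2, 11, 3, 10), 1L)
  # bulge (+1) + interior (+1) merging into one interior (+1): dE = -1 < 0
  s2 <- "GAGAGAAAACAAACC"
  expect_equal(delta_merge_internal(toy_model, s2, 1, 15, 3, 14, 5, 10), 0L)
  # merged loop beyond the size cap: removal leaves the ensemble, delta = 1
  s3 <- paste0("GG", strrep("A", 16), "GC", strrep("A", 16), "CC")
  expect_equal(delta_merge_internal(toy_model, s3, 1, 38, 2, 37, 19, 20), 1L)
})

test_that("worked micro-example: GCAAAAGC under the toy model", {
  lt <- compute_locopt_tables(toy_model, "GCAAAAGC")
  expect_equal(lt$Ztot, 2.0, tolerance = 1e-12)
  expect_true(lt$empty_locopt)
  pf <- locopt_partition_function(toy_model, "GCAAAAGC")
  expect_equal(pf$ratio, 2 / (2 + 2 * exp(-2 / 0.6)), tolerance = 1e-12)
  expect_equal(count_structures(toy_model, "GCAAAAGC", "all"), 4)
  expect_equal(count_structures(toy_model, "GCAAAAGC", "locopt"), 2)
  expect_equal(compute_locopt_tables(toy_model, "AAAAAAAA")$Ztot, 1.0)
  expect_equal(locopt_partition_function(toy_model, "AAAAAAAA")$ratio, 1.0)
})

test_that("DP equals the enumeration oracle on random sequences", {
  for (model in list(toy_model, turner_model)) {
    tol <- if (identical(model$name, "toy")) 1e-8 else 1e-6
    for (s in rand_seqs(12, 10, 22, seed = 31)) {
      b <- brute_ensemble(model, s)
      expect_equal(compute_locopt_tables(model, s)$Ztot, b$Z_locopt,
                   tolerance = tol)
      expect_identical(count_structures(model, s, "locopt"), b$count_locopt)
      expect_identical(count_structures(model, s, "all"), b$count_all)
    }
  }
})

test_that("locally optimal ensemble is a subset of the full ensemble", {
  for (s in rand_seqs(10, 15, 40, seed = 32)) {
    pf <- locopt_partition_function(turner_model, s)
    expect_lte(pf$Ztot, pf$Z * (1 + 1e-12))
    expect_gt(pf$ratio, 0)
    expect_lte(count_structures(turner_model, s, "locopt"),
               count_structures(turner_model, s, "all"))
  }
})

test_that("tail cap 4 matches tail cap 10 except through long-tail deltas", {
  # where the two differ, the coarser window can only overcount
  for (model in list(toy_model, turner_model)) {
    for (s in rand_seqs(8, 12, 24, seed = 33)) {
      z10 <- compute_locopt_tables(model, s, max_tail = 10)$Ztot
      z4 <- compute_locopt_tables(model, s, max_tail = 4)$Ztot
      expect_gte(z4, z10 - 1e-9 * z10)
      expect_equal(z10, brute_partition_function(model, s, "locopt"),
                   tolerance = 1e-8)
    }
  }
})

test_that("empty-structure handling matches the direct neighborhood check", {
  for (s in c("AAAAAAAA", rand_seqs(8, 8, 20, seed = 34))) {
    lt <- compute_locopt_tables(toy_model, s)
    expect_identical(lt$empty_locopt,
                     is_locally_optimal(toy_model, s,
                                        secondary_structure(NULL, nchar(s))))
  }
})

test_that("locally optimal sampling honors its contract", {
  sm <- sample_locopt(toy_model, "GCAAAAGC", k = 10000, seed = 8)
  fr <- table(sm$structure) / nrow(sm)
  expect_setequal(names(fr), c("........", "((....))"))
  expect_equal(unname(fr["........"]), 0.5, tolerance = 0.03)
  a <- sample_locopt(turner_model, "GGGCAAAAGCCCAAAGGGCAAAAGCCC", k = 50, seed = 3)
  b <- sample_locopt(turner_model, "GGGCAAAAGCCCAAAGGGCAAAAGCCC", k = 50, seed = 3)
  expect_identical(a, b)
  # every sample is locally optimal (definition-level recheck)
  for (s in rand_seqs(3, 14, 20, seed = 35)) {
    sm <- sample_locopt(turner_model, s, k = 60, seed = 5)
    for (db in unique(sm$structure)) {
      expect_true(is_locally_optimal(turner_model, s, db))
    }
  }
})
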