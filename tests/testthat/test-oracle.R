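test_that("enumeration produces every structure exactly once", {
  st <- enumerate_structures("GCAAAAGC")
  expect_setequal(st, c("........", "(......)", ".(....).", "((....))"))
  expect_equal(enumerate_structures("AAAAA"), ".....")
  for (s in rand_seqs(6, 10, 18, seed = 41)) {
    st <- enumerate_structures(s)
    expect_equal(anyDuplicated(st), 0)
    expect_equal(length(st), count_structures(toy_model, s, "all"))
  }
  expect_error(enumerate_structures(strrep("A", 31)), "cap")
})

test_that("brute locally optimal set matches hand checks", {
  lo <- brute_locopt_set(toy_model, "GCAAAAGC")
  expect_setequal(lo$structure, c("........", "((....))"))
  expect_equal(brute_locopt_set(toy_model, "AAAAAAAA")$structure, "........")
  # always a subset of all structures
  for (s in rand_seqs(4, 10, 16, seed = 42)) {
    expect_true(all(brute_locopt_set(turner_model, s)$structure %in%
                      enumerate_structures(s)))
  }
})

test_that("brute partition sums match their definitions", {
  expect_equal(brute_partition_function(toy_model, "GCAAAAGC", "all"),
               2 + 2 * exp(-2 / 0.6), tolerance = 1e-12)
  expect_equal(brute_partition_function(toy_model, "GCAAAAGC", "locopt"), 2,
               tolerance = 1e-12)
  # zero energies: the partition function is the count
  for (s in rand_seqs(3, 10, 14, seed = 43)) {
    expect_equal(brute_partition_function(zero_model, s, "all"),
                 length(enumerate_structures(s)))
  }
})

test_that("R-level local optimality agrees with the C++ oracle filter", {
  for (model in list(toy_model, turner_model)) {
    for (s in rand_seqs(3, 10, 14, seed = 44)) {
      all_st <- enumerate_structures(s)
      lo_ref <- vapply(all_st, function(d) is_locally_optimal(model, s, d),
                       logical(1))
      lo_cpp <- all_st %in% brute_locopt_set(model, s)$structure
      expect_identical(unname(lo_ref), lo_cpp)
    }
  }
})
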