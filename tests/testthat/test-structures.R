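test_that("dot-bracket codec round-trips and rejects bad input", {
  st <- parse_dot_bracket("((....))")
  expect_equal(st$pairs, matrix(c(1L, 2L, 8L, 7L), 2, 2,
                                dimnames = list(NULL, c("i", "j"))))
  expect_equal(format_dot_bracket(secondary_structure(rbind(c(1, 8)), 8)),
               "(......)")
  for (db in c("........", "(......)", "((....))", "((...))((...))")) {
    expect_equal(format_dot_bracket(parse_dot_bracket(db)), db)
  }
  expect_error(parse_dot_bracket("((...)"), "unbalanced")
  expect_error(parse_dot_bracket("(....))"), "unbalanced")
  expect_error(parse_dot_bracket("((..x.))"), "foreign")
})

test_that("structure constraints are enforced", {
  expect_error(secondary_structure(rbind(c(1, 4)), 8), "theta")
  expect_error(secondary_structure(rbind(c(1, 8), c(1, 7)), 8), "triple")
  expect_error(secondary_structure(rbind(c(1, 7), c(3, 9)), 10), "crossing")
  expect_error(validate_structure("GAAAAAAC", parse_dot_bracket("((....))")),
               "non-canonical")
})

test_that("loop decomposition partitions the structure", {
  loops <- loop_decomposition(parse_dot_bracket("((....))"))
  kinds <- vapply(loops, `[[`, character(1), "kind")
  expect_setequal(kinds, c("internal", "hairpin", "external"))
  int <- loops[[which(kinds == "internal")]]
  expect_equal(int$closing, c(1, 8))
  expect_equal(unname(int$branches[1, ]), c(2, 7))

  loops0 <- loop_decomposition(secondary_structure(NULL, 8))
  expect_length(loops0, 1)
  expect_equal(loops0[[1]]$kind, "external")
  expect_equal(loops0[[1]]$unpaired, 1:8)

  # three helices under one closing pair: exactly one multiloop with two
  # interior branches
  ml <- parse_dot_bracket("((....)(....))")
  kinds <- vapply(loop_decomposition(ml), `[[`, character(1), "kind")
  expect_equal(sum(kinds == "multiloop"), 1)
  mloop <- loop_decomposition(ml)[[which(kinds == "multiloop")]]
  expect_equal(nrow(mloop$branches), 2)
})

test_that("neighborhood matches the add/remove move set", {
  nb <- neighbors("GCAAAAGC", secondary_structure(NULL, 8))
  expect_setequal(vapply(nb, format_dot_bracket, character(1)),
                  c("(......)", ".(....)."))
  nb2 <- neighbors("GCAAAAGC", "((....))")
  expect_setequal(vapply(nb2, format_dot_bracket, character(1)),
                  c("(......)", ".(....)."))
  expect_length(neighbors("AAAAAAAA", secondary_structure(NULL, 8)), 0)
})

test_that("neighborhood is symmetric", {
  for (s in rand_seqs(5, 10, 16, seed = 11)) {
    st <- parse_dot_bracket(sample_all(toy_model, s, k = 1, seed = 3)$structure)
    for (nb in neighbors(s, st)) {
      back <- vapply(neighbors(s, nb), format_dot_bracket, character(1))
      expect_true(format_dot_bracket(st) %in% back)
    }
  }
})

test_that("local optimality hand checks", {
  expect_true(is_locally_optimal(toy_model, "GCAAAAGC", "........"))
  expect_false(is_locally_optimal(toy_model, "GCAAAAGC", "(......)"))
  expect_true(is_locally_optimal(toy_model, "GCAAAAGC", "((....))"))
  # below the minimal pairing length only the empty structure exists
  expect_true(is_locally_optimal(toy_model, "GCA", secondary_structure(NULL, 3)))
})

test_that("base pair distance is the symmetric difference size", {
  a <- secondary_structure(rbind(c(1, 8)), 8)
  b <- secondary_structure(rbind(c(2, 7)), 8)
  expect_equal(base_pair_distance(a, b), 2)
  expect_equal(base_pair_distance(a, a), 0)
  expect_equal(base_pair_distance(secondary_structure(NULL, 8),
                                  parse_dot_bracket("((....))")), 2)
  expect_error(base_pair_distance(a, secondary_structure(NULL, 9)), "length")
})
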