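test_that("toy model reproduces its defining constants", {
  expect_equal(toy_model$RT, 0.6)
  expect_equal(hairpin_energy(toy_model, "GCAAAAGC", 1, 8), 2.0)
  expect_equal(hairpin_energy(toy_model, "GCAAAAGC", 2, 7), 2.0)
  # stack, bulge and interior loop energies are flat
  expect_equal(internal_loop_energy(toy_model, "GCGCAAAAGCGC", 1, 12, 2, 11), -2.0)
  expect_equal(internal_loop_energy(toy_model, "GAGAAAAAAAACC", 1, 13, 3, 12), 1.0)
  expect_equal(internal_loop_energy(toy_model, "GAGAAAAAAAACAAC", 1, 15, 3, 12), 1.0)
})

test_that("energy accessors reject invalid geometry", {
  expect_error(hairpin_energy(toy_model, "GAACAAAA", 1, 4), "smaller than theta")
  expect_error(hairpin_energy(toy_model, "GCAAAAGC", 1, 5), "non-canonical")
  # internal loop beyond the size cap
  s <- paste0("G", strrep("A", 17), "GC", strrep("A", 16), "C")
  expect_error(internal_loop_energy(toy_model, s, 1, 37, 19, 20), "exceeds cap")
  expect_error(multiloop_energy(toy_model, -1, 3), "negative")
})

test_that("multiloop energy is affine with per-pair AU/GU penalties", {
  expect_equal(multiloop_energy(toy_model, 2, 4), 3.0 + 0.1 * 4 + 0.4 * 3)
  expect_equal(multiloop_energy(toy_model, 2, 0), 3.0 + 1.2)
  base <- multiloop_energy(turner_model, 2, 3, c("GC", "CG", "GC"))
  with_au <- multiloop_energy(turner_model, 2, 3, c("GC", "AU", "GU"))
  expect_equal(with_au - base, 2 * turner_model$au_gu)
})

test_that("turner tables have the expected sign pattern", {
  expect_true(all(turner_model$hairpin[3:30] > 0))
  expect_true(all(turner_model$bulge > 0))
  expect_true(all(turner_model$interior[2:30] > 0))
  wc <- c("AU", "CG", "GC", "UA")
  expect_true(all(turner_model$stack[wc, wc] < 0))
  expect_false(isSymmetric(turner_model$stack))
  # physical symmetry: reading the stack from the other strand
  rev_pair <- c(AU = "UA", CG = "GC", GC = "CG", UA = "AU", GU = "UG", UG = "GU")
  for (a in rownames(turner_model$stack))
    for (b in colnames(turner_model$stack))
      expect_equal(turner_model$stack[a, b],
                   turner_model$stack[rev_pair[b], rev_pair[a]])
})

test_that("parameter loading errors are informative", {
  expect_error(load_parameters("toy", temperature = 25), "37")
  expect_error(load_parameters("/nonexistent/file.par"), "unreadable")
  # truncated interior block
  tmp <- tempfile(fileext = ".par")
  lines <- readLines(system.file("extdata", "turner_nn.par", package = "locopt"))
  cut <- grep("^# interior$", lines)
  writeLines(c(lines[1:(cut + 1)], "# ML_params", " 3.4 0.0 0.4",
               "# NINIO", " 0.5 3.0", "# Terminal_AU", " 0.5", "# END"), tmp)
  expect_error(load_parameters(tmp), "interior")
})

test_that("structure energies follow the loop decomposition", {
  expect_equal(structure_energy(toy_model, "GCAAAAGC", "........"), 0)
  expect_equal(structure_energy(toy_model, "GCAAAAGC", "(......)"), 2.0)
  expect_equal(structure_energy(toy_model, "GCAAAAGC", "((....))"), 0)
  # energy is invariant under the order pairs are listed
  s1 <- secondary_structure(rbind(c(1, 8), c(2, 7)), 8)
  s2 <- secondary_structure(rbind(c(2, 7), c(1, 8)), 8)
  expect_equal(structure_energy(toy_model, "GCAAAAGC", s1),
               structure_energy(toy_model, "GCAAAAGC", s2))
})

test_that("R and C++ energy evaluation agree on sampled structures", {
  for (model in list(toy_model, turner_model)) {
    for (s in rand_seqs(4, 15, 30, seed = 301)) {
      smp <- sample_all(model, s, k = 25, seed = 7)
      for (db in unique(smp$structure)) {
        st <- parse_dot_bracket(db)
        eR <- structure_energy(model, s, st)
        eC <- locopt:::cpp_structure_energy(locopt:::encode_sequence(s),
                                   unclass(model), st$pairs)
        expect_equal(eR, eC, tolerance = 1e-12)
      }
    }
  }
})
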