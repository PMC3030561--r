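# shared fixtures: models and deterministic random sequences
toy_model <- load_parameters("toy")
turner_model <- load_parameters("turner")

# a zero-energy variant of the toy model: every Boltzmann factor is 1, so
# partition functions equal structure counts
zero_model <- local({
  m <- toy_model
  m$hairpin[] <- 0
  m$bulge[] <- 0
  m$interior[] <- 0
  m$stack[] <- 0
  m$ml_close <- 0
  m$ml_unpaired <- 0
  m$ml_branch <- 0
  m$au_gu <- 0
  m
})

rand_seqs <- function(k, nmin, nmax, seed) {
  set.seed(seed)
  vapply(seq_len(k), function(i) {
    n <- sample(nmin:nmax, 1)
    paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
  }, character(1))
}

# designed strong-hairpin sequences: complementary stems with short loops
designed_hairpins <- c(
  "GGGGGCAAAAGCCCCC",
  "GGCGGCAUAAGCCGCC",
  "CCCCGAAUUACGGGGA",
  "GCGCGCUUCGGCGCGC",
  "AGGGGCAAGAGCCCCU",
  "GGCCGGAAAACCGGCC",
  "CGCGGGUUUUCCCGCG",
  "GGGCGCAAUAGCGCCC",
  "UGGGGCGAAAGCCCCA",
  "CCGGCGUUCGCGCCGG"
)
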