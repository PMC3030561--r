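Package: locopt
Title: Partition Function and Boltzmann Sampling for Locally Optimal RNA
    Secondary Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes the partition function, exact counts and Boltzmann
    samples over the subensemble of locally optimal RNA secondary structures
    (kinetic traps) under a nearest-neighbor energy model without dangling
    ends, using conditionally-optimal dynamic programming with tail-indexed
    multiloop recursions. Also provides McCaskill's partition function and
    base-pair probabilities for the full ensemble, ensemble diversity
    statistics, maximum expected accuracy structure prediction from full,
    locally-optimal and combined pairing probabilities, a brute-force
    enumeration oracle for small sequences, and experiment harnesses for
    random-sequence studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
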