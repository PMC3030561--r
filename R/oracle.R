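#' Exhaustively enumerate all secondary structures
#'
#' Ground truth by interval recursion (position 1 unpaired, or paired to
#' each feasible partner): every structure satisfying the secondary
#' structure constraints is produced exactly once. Feasible for short
#' sequences only.
#'
#' @param seq RNA sequence string.
#' @param cap refuse sequences longer than this (default 30).
#' @return a character vector of dot-bracket strings, duplicate-free.
#' @examples
#' enumerate_structures("GCAAAAGC")  # 4 structures
#' @export
enumerate_structures <- function(seq, cap = 30) {
  codes <- encode_sequence(seq)
  if (length(codes) > cap)
    stop("sequence of length ", length(codes),
         " exceeds the enumeration cap (", cap, ")")
  as.character(cpp_enumerate(codes, .model_list(load_parameters("toy"))))
}

#' Brute-force summary of the full and locally optimal ensembles
#'
#' Enumerates every structure, evaluates its energy by loop decomposition,
#' and filters the locally optimal subset by the definition-level
#' neighborhood check. This is the oracle against which the dynamic
#' programming engine is certified.
#'
#' @inheritParams structure_energy
#' @param cap refuse sequences longer than this (default 30).
#' @param collect_all also return every structure and energy (not only the
#'   locally optimal subset).
#' @return a list with `count_all`, `count_locopt`, `Z_all`, `Z_locopt`
#'   (Boltzmann sums accumulated in sorted energy order), `locopt_structures`
#'   and `locopt_energies`, plus `all_structures`/`all_energies` when
#'   `collect_all = TRUE`.
#' @export
brute_ensemble <- function(model, seq, cap = 30, collect_all = FALSE) {
  codes <- encode_sequence(seq)
  if (length(codes) > cap)
    stop("sequence of length ", length(codes),
         " exceeds the enumeration cap (", cap, ")")
  cpp_brute(codes, .model_list(model), collect_all)
}

#' Brute-force locally optimal set
#'
#' @inheritParams brute_ensemble
#' @return a data frame with columns `structure` and `energy`, one row per
#'   locally optimal structure.
#' @examples
#' toy <- load_parameters("toy")
#' brute_locopt_set(toy, "GCAAAAGC")  # empty structure and the full helix
#' @export
brute_locopt_set <- function(model, seq, cap = 30) {
  b <- brute_ensemble(model, seq, cap)
  data.frame(structure = as.character(b$locopt_structures),
             energy = as.numeric(b$locopt_energies),
             stringsAsFactors = FALSE)
}

#' Brute-force partition function
#'
#' Boltzmann sum `sum exp(-E/RT)` over all structures or over the locally
#' optimal subset, with terms added in sorted energy order for
#' reproducibility.
#'
#' @inheritParams brute_ensemble
#' @param subset `"all"` or `"locopt"`.
#' @return the partition function value.
#' @export
brute_partition_function <- function(model, seq, subset = c("all", "locopt"),
                                     cap = 30) {
  subset <- match.arg(subset)
  b <- brute_ensemble(model, seq, cap)
  if (subset == "all") b$Z_all else b$Z_locopt
}
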