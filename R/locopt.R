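#' Precompute delta flags for the locally optimal recursions
#'
#' The conditional-optimality recursions gate every extension on indicator
#' ("delta") checks that no single base-pair addition or removal lowers the
#' energy. This returns the precomputable ones: per-hairpin addition flags
#' (`hp_ok`), per-internal-loop addition checks (`il_ok`, evaluated on
#' demand) and tail-window flags for additions that enclose a multiloop or
#' external branch (`tail_ok`). Flags depend only on the sequence, the
#' energy model and the listed indices.
#'
#' @inheritParams structure_energy
#' @param max_tail tail window: unpaired tails are tracked exactly up to
#'   this length (buckets `0..max_tail` plus one "longer" bucket). 10 by
#'   default; 4 gives a faster, slightly coarser recursion.
#' @return an object of class `delta_flags`: a list with the logical matrix
#'   `hp_ok`, the function `il_ok(i, j, k, l)`, and the function
#'   `tail_ok(i, j, context)` returning the `(max_tail+1) x (max_tail+1)`
#'   window flag matrix for branch pair `(i, j)` in context `"ml"` or
#'   `"ext"`.
#' @export
precompute_delta_flags <- function(model, seq, max_tail = 10) {
  stopifnot(max_tail %in% c(4L, 10L, 4, 10))
  codes <- encode_sequence(seq)
  ml <- .model_list(model)
  structure(list(
    n = length(codes),
    max_tail = as.integer(max_tail),
    hp_ok = cpp_hp_ok_matrix(codes, ml),
    il_ok = function(i, j, k, l) cpp_il_ok(codes, ml, i, j, k, l),
    tail_ok = function(i, j, context = c("ml", "ext")) {
      context <- match.arg(context)
      cpp_tail_ok(codes, ml, i, j, as.integer(max_tail), context)
    }
  ), class = "delta_flags")
}

#' Delta for removing a base pair between two internal loops
#'
#' For nested pairs `(i,j)`, `(k,l)`, `(m,n)` forming internal loops
#' `(i,j;k,l)` and `(k,l;m,n)`, removing `(k,l)` merges them into the
#' single loop `(i,j;m,n)`. Returns 1 iff the removal does not lower the
#' energy: `EL(i,j;m,n) - EL(i,j;k,l) - EL(k,l;m,n) >= 0` (ties keep
#' optimality). If the merged loop exceeds the internal-loop size cap the
#' removal leaves the ensemble and is treated as non-lowering.
#'
#' @inheritParams internal_loop_energy
#' @param m,n innermost pair indices, nested within `(k, l)`.
#' @return integer 0 or 1.
#' @export
delta_merge_internal <- function(model, seq, i, j, k, l, m, n) {
  if (!(i < k && k < m && m < n && n < l && l < j))
    stop("pairs must be strictly nested: (i,j) > (k,l) > (m,n)")
  merged_size <- (m - i - 1) + (j - n - 1)
  if (merged_size > model$max_internal) return(1L)
  d <- internal_loop_energy(model, seq, i, j, m, n) -
    internal_loop_energy(model, seq, i, j, k, l) -
    internal_loop_energy(model, seq, k, l, m, n)
  as.integer(d >= -.EPS)
}

#' Fill the conditionally locally optimal tables
#'
#' Runs the full conditional-optimality recursion: locally optimal hairpins
#' (`ZHP`), internal-loop-topped structures indexed by their outermost two
#' pairs (`ZIL`, exposed here through its branch aggregates `Sml`/`Sext`),
#' closed locally optimal multiloops (`ZbML`) built by gluing tail-indexed
#' one-component pieces, and the external-loop accumulation yielding the
#' total `Ztot`. The empty structure contributes iff it is locally optimal.
#'
#' @inheritParams precompute_delta_flags
#' @param flags optionally the output of [precompute_delta_flags()] for the
#'   same sequence and `max_tail` (interface symmetry; the engine
#'   recomputes its flags internally).
#' @return an object of class `locopt_tables` with elements `Ztot`,
#'   `empty_locopt`, and matrices `ZHP`, `ZbML`, `Sml`, `Sext`.
#' @examples
#' toy <- load_parameters("toy")
#' compute_locopt_tables(toy, "GCAAAAGC")$Ztot  # exactly 2
#' @export
compute_locopt_tables <- function(model, seq, flags = NULL, max_tail = 10) {
  if (!is.null(flags)) {
    stopifnot(inherits(flags, "delta_flags"))
    max_tail <- flags$max_tail
  }
  codes <- encode_sequence(seq)
  out <- cpp_locopt(codes, .model_list(model), FALSE, as.integer(max_tail))
  out$seq <- normalize_sequence(seq)
  out$max_tail <- as.integer(max_tail)
  class(out) <- "locopt_tables"
  out
}

#' @export
print.locopt_tables <- function(x, ...) {
  cat("<locopt_tables> n =", nchar(x$seq), " Ztot =",
      format(x$Ztot, digits = 8), "\n")
  invisible(x)
}

#' Partition function over locally optimal structures
#'
#' @inheritParams precompute_delta_flags
#' @return a list with `Ztot` (Boltzmann sum over locally optimal
#'   structures), `Z` (over all structures) and their ratio
#'   `Ztot / Z` in (0, 1].
#' @examples
#' toy <- load_parameters("toy")
#' locopt_partition_function(toy, "GCAAAAGC")$ratio  # ~0.9656
#' @export
locopt_partition_function <- function(model, seq, max_tail = 10) {
  codes <- encode_sequence(seq)
  ml <- .model_list(model)
  Ztot <- cpp_locopt(codes, ml, FALSE, as.integer(max_tail))$Ztot
  Z <- cpp_mccaskill(codes, ml, FALSE)$Ztotal
  list(Ztot = Ztot, Z = Z, ratio = Ztot / Z)
}

#' Count secondary structures
#'
#' `mode = "all"` counts all secondary structures by running the inside
#' recursions with every Boltzmann factor replaced by 1; `mode = "locopt"`
#' counts locally optimal structures by running the conditional recursions
#' with unit weights while the delta checks are still evaluated on the
#' 37 C energies (local optimality is an energetic notion; only the
#' weights are removed). Counts are exact integers up to 2^53 and
#' correctly rounded doubles beyond.
#'
#' @inheritParams precompute_delta_flags
#' @param mode `"all"` or `"locopt"`.
#' @return a count (numeric).
#' @examples
#' toy <- load_parameters("toy")
#' count_structures(toy, "GCAAAAGC", "all")     # 4
#' count_structures(toy, "GCAAAAGC", "locopt")  # 2
#' @export
count_structures <- function(model, seq, mode = c("all", "locopt"),
                             max_tail = 10) {
  mode <- match.arg(mode)
  codes <- encode_sequence(seq)
  ml <- .model_list(model)
  if (mode == "all") cpp_mccaskill(codes, ml, TRUE)$Ztotal
  else cpp_locopt(codes, ml, TRUE, as.integer(max_tail))$Ztot
}

#' Boltzmann sampling over locally optimal structures
#'
#' Draws `k` i.i.d. structures with probability `exp(-E(S)/RT) / Ztot`
#' restricted to locally optimal structures, by stochastic traceback
#' through the conditional-optimality recursions. Every returned structure
#' is locally optimal.
#'
#' @inheritParams sample_all
#' @param tables optionally a [compute_locopt_tables()] result for the same
#'   sequence (interface symmetry; the engine refills its tables).
#' @param max_tail tail window, see [precompute_delta_flags()].
#' @return a data frame with columns `structure` and `energy`.
#' @export
sample_locopt <- function(model, seq, tables = NULL, k = 1000, seed = NULL,
                          max_tail = 10) {
  stopifnot(k >= 1)
  if (!is.null(tables)) {
    stopifnot(inherits(tables, "locopt_tables"))
    max_tail <- tables$max_tail
  }
  codes <- encode_sequence(seq)
  out <- .with_seed(seed, cpp_sample_locopt(codes, .model_list(model),
                                            as.integer(k), as.integer(max_tail)))
  data.frame(structure = as.character(out$structure),
             energy = as.numeric(out$energy),
             stringsAsFactors = FALSE)
}
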