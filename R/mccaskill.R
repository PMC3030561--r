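# run code with a locally-scoped RNG seed, restoring global state afterwards
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  code
}

#' McCaskill inside recursions over all secondary structures
#'
#' Fills the interval partition function `Z`, the pair-constrained `Zb`,
#' and the multiloop tables `ZM1` (exactly one component, 5' end paired)
#' and `ZM` (one or more components), by increasing interval length.
#' `Z[1, n]` equals the Boltzmann sum over all secondary structures
#' (internal loops capped at `model$max_internal`, as is standard).
#'
#' @inheritParams structure_energy
#' @return an object of class `mccaskill_tables`: a list with matrices
#'   `Z`, `Zb`, `ZM`, `ZM1` (1-based interval indexing `[i, j]`) and the
#'   scalar `Ztotal`.
#' @examples
#' toy <- load_parameters("toy")
#' compute_inside(toy, "GCAAAAGC")$Ztotal  # 2 + 2 exp(-2 / 0.6)
#' @export
compute_inside <- function(model, seq) {
  codes <- encode_sequence(seq)
  out <- cpp_mccaskill(codes, .model_list(model), FALSE)
  out$seq <- normalize_sequence(seq)
  out$model_name <- model$name
  class(out) <- "mccaskill_tables"
  out
}

#' @export
print.mccaskill_tables <- function(x, ...) {
  cat("<mccaskill_tables> n =", nchar(x$seq), " Z =",
      format(x$Ztotal, digits = 8), "\n")
  invisible(x)
}

#' Exact base-pair and unpaired probabilities
#'
#' Computes `p[i, j] = sum over structures containing (i,j) of
#' exp(-E/RT) / Z` by the standard outside recursion, and
#' `q[i] = 1 - sum_j p[i, j]`.
#'
#' @inheritParams structure_energy
#' @param tables optionally, tables from [compute_inside()] for the same
#'   sequence (accepted for interface symmetry; the outside pass recomputes
#'   the inside tables internally).
#' @return a list with the symmetric matrix `p` and vector `q`; for every
#'   position the sum rule `q[i] + sum_j p[i, j] = 1` holds.
#' @export
pair_probabilities <- function(model, seq, tables = NULL) {
  if (!is.null(tables) && !identical(tables$seq, normalize_sequence(seq)))
    stop("'tables' were computed for a different sequence")
  codes <- encode_sequence(seq)
  out <- cpp_pair_probabilities(codes, .model_list(model))
  structure(list(p = out$p, q = as.numeric(out$q)),
            class = "pair_probabilities")
}

#' Boltzmann sampling over all secondary structures
#'
#' Draws `k` i.i.d. structures with probability `exp(-E(S)/RT) / Z` by
#' stochastic traceback through the inside recursions (inverse-CDF
#' selection over each recursion's alternatives in a fixed order).
#'
#' @inheritParams pair_probabilities
#' @param k number of samples.
#' @param seed optional integer seed; the same seed reproduces the sample
#'   list exactly.
#' @return a data frame with columns `structure` (dot-bracket) and
#'   `energy` (kcal/mol).
#' @export
sample_all <- function(model, seq, tables = NULL, k = 1000, seed = NULL) {
  stopifnot(k >= 1)
  codes <- encode_sequence(seq)
  out <- .with_seed(seed, cpp_sample_all(codes, .model_list(model), as.integer(k)))
  data.frame(structure = as.character(out$structure),
             energy = as.numeric(out$energy),
             stringsAsFactors = FALSE)
}
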