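#' Construct a secondary structure
#'
#' A secondary structure on a sequence of length `n` is a set of base pairs
#' `(i, j)`, `i < j`, such that every hairpin loop encloses at least three
#' unpaired bases (`j - i > 3`), no index occurs in two pairs (no base
#' triples) and no two pairs cross (no pseudoknots). Indices are 1-based
#' and inclusive.
#'
#' @param pairs a two-column matrix of pair indices (or `NULL`/empty for the
#'   empty structure).
#' @param n sequence length.
#' @return an object of class `rna_structure` with fields `n` and `pairs`.
#' @examples
#' secondary_structure(rbind(c(1, 8), c(2, 7)), n = 8)
#' @export
secondary_structure <- function(pairs = NULL, n) {
  n <- as.integer(n)
  if (is.null(pairs) || length(pairs) == 0) {
    pairs <- matrix(integer(0), 0, 2)
  } else {
    pairs <- matrix(as.integer(pairs), ncol = 2)
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  }
  colnames(pairs) <- c("i", "j")
  if (nrow(pairs) > 0) {
    if (any(pairs < 1) || any(pairs > n))
      stop("pair index out of range 1..", n)
    if (any(pairs[, 2] <= pairs[, 1]))
      stop("pairs must satisfy i < j")
    if (any(pairs[, 2] - pairs[, 1] <= .THETA))
      stop("hairpin loop smaller than theta = ", .THETA)
    idx <- c(pairs)
    if (anyDuplicated(idx))
      stop("base triple: an index occurs in two pairs")
    if (nrow(pairs) > 1) {
      for (r in seq_len(nrow(pairs) - 1)) {
        a <- pairs[r, ]
        rest <- pairs[(r + 1):nrow(pairs), , drop = FALSE]
        inside_i <- rest[, 1] > a[1] & rest[, 1] < a[2]
        inside_j <- rest[, 2] > a[1] & rest[, 2] < a[2]
        if (any(inside_i != inside_j))
          stop("crossing pairs (pseudoknot) are not allowed")
      }
    }
  }
  structure(list(n = n, pairs = pairs), class = "rna_structure")
}

#' Coerce to an rna_structure
#'
#' @param x an `rna_structure`, a dot-bracket string, or a two-column pair
#'   matrix.
#' @param n sequence length (required unless `x` carries one).
#' @return an `rna_structure`.
#' @export
as_rna_structure <- function(x, n = NULL) {
  if (inherits(x, "rna_structure")) return(x)
  if (is.character(x) && length(x) == 1L) return(parse_dot_bracket(x))
  if (is.null(n)) stop("'n' required to interpret a pair matrix")
  secondary_structure(x, n)
}

#' @export
print.rna_structure <- function(x, ...) {
  cat("<rna_structure> n =", x$n, "\n ", format_dot_bracket(x), "\n")
  invisible(x)
}

#' Parse dot-bracket notation
#'
#' @param text a string over `.`, `(` and `)` (Vienna convention).
#' @return an [rna_structure][secondary_structure].
#' @examples
#' parse_dot_bracket("((....))")
#' @export
parse_dot_bracket <- function(text) {
  if (!is.character(text) || length(text) != 1L)
    stop("dot-bracket input must be a single string")
  ch <- strsplit(text, "")[[1]]
  bad <- setdiff(unique(ch), c(".", "(", ")"))
  if (length(bad) > 0)
    stop("parse error: foreign character(s) in dot-bracket string: ",
         paste(bad, collapse = " "))
  stack <- integer(0)
  pairs <- matrix(integer(0), 0, 2)
  for (k in seq_along(ch)) {
    if (ch[k] == "(") stack <- c(stack, k)
    else if (ch[k] == ")") {
      if (length(stack) == 0) stop("parse error: unbalanced ')' at position ", k)
      pairs <- rbind(pairs, c(stack[length(stack)], k))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack) > 0)
    stop("parse error: unbalanced '(' at position ", stack[length(stack)])
  secondary_structure(pairs, length(ch))
}

#' Render a structure in dot-bracket notation
#'
#' @param structure an [rna_structure][secondary_structure].
#' @return a dot-bracket string, one character per position.
#' @export
format_dot_bracket <- function(structure) {
  ch <- rep(".", structure$n)
  if (nrow(structure$pairs) > 0) {
    ch[structure$pairs[, 1]] <- "("
    ch[structure$pairs[, 2]] <- ")"
  }
  paste(ch, collapse = "")
}

# mate vector: mate[i] = j if (i,j) or (j,i) paired, else 0
.mate_vector <- function(structure) {
  mate <- integer(structure$n)
  if (nrow(structure$pairs) > 0) {
    mate[structure$pairs[, 1]] <- structure$pairs[, 2]
    mate[structure$pairs[, 2]] <- structure$pairs[, 1]
  }
  mate
}

#' Validate a structure against a sequence
#'
#' Checks that every base pair is canonical (Watson-Crick or wobble) for the
#' given sequence.
#'
#' @inheritParams structure_energy
#' @return invisibly `TRUE`; errors otherwise.
#' @export
validate_structure <- function(seq, structure) {
  sq <- normalize_sequence(seq)
  if (nchar(sq) != structure$n)
    stop("sequence length ", nchar(sq), " does not match structure n = ",
         structure$n)
  if (nrow(structure$pairs) > 0) {
    ch <- strsplit(sq, "")[[1]]
    for (r in seq_len(nrow(structure$pairs))) {
      i <- structure$pairs[r, 1]; j <- structure$pairs[r, 2]
      if (.pair_code(ch[i], ch[j]) == 0L)
        stop("non-canonical pair (", i, ",", j, "): ", ch[i], "-", ch[j])
    }
  }
  invisible(TRUE)
}

#' Unique loop decomposition of a secondary structure
#'
#' Partitions a structure into hairpin, internal (stacks, bulges, interior
#' loops), multiloop and external loops. Every base pair closes exactly one
#' loop; the external region is listed once (last).
#'
#' @param structure an [rna_structure][secondary_structure].
#' @return a list of loops, each a list with elements `kind` (one of
#'   `"hairpin"`, `"internal"`, `"multiloop"`, `"external"`), `closing`
#'   (`c(i, j)`, absent for the external loop), `branches` (two-column
#'   matrix of interior branch pairs) and `unpaired` (integer positions).
#' @export
loop_decomposition <- function(structure) {
  mate <- .mate_vector(structure)
  n <- structure$n
  scan_region <- function(from, to) {
    # branches and unpaired positions strictly within [from, to]
    branches <- matrix(integer(0), 0, 2)
    unpaired <- integer(0)
    k <- from
    while (k <= to) {
      if (mate[k] > k) {
        branches <- rbind(branches, c(k, mate[k]))
        k <- mate[k] + 1L
      } else {
        unpaired <- c(unpaired, k)
        k <- k + 1L
      }
    }
    list(branches = branches, unpaired = unpaired)
  }
  loops <- list()
  if (nrow(structure$pairs) > 0) {
    for (r in seq_len(nrow(structure$pairs))) {
      i <- structure$pairs[r, 1]; j <- structure$pairs[r, 2]
      reg <- scan_region(i + 1L, j - 1L)
      kind <- if (nrow(reg$branches) == 0) "hairpin"
              else if (nrow(reg$branches) == 1) "internal"
              else "multiloop"
      loops[[length(loops) + 1L]] <- list(
        kind = kind, closing = unname(c(i, j)),
        branches = reg$branches, unpaired = reg$unpaired)
    }
  }
  ext <- scan_region(1L, n)
  loops[[length(loops) + 1L]] <- list(
    kind = "external", closing = NULL,
    branches = ext$branches, unpaired = ext$unpaired)
  loops
}

#' Single base-pair move neighborhood
#'
#' All structures obtained from `structure` by removing one pair or by
#' adding one canonical pair `(i, j)` with `j - i > 3`, both ends unpaired
#' and non-crossing. No shift moves.
#'
#' @inheritParams structure_energy
#' @return a list of [rna_structure][secondary_structure] objects.
#' @export
neighbors <- function(seq, structure) {
  sq <- normalize_sequence(seq)
  structure <- as_rna_structure(structure, nchar(sq))
  validate_structure(sq, structure)
  ch <- strsplit(sq, "")[[1]]
  n <- structure$n
  mate <- .mate_vector(structure)
  out <- list()
  # removals
  if (nrow(structure$pairs) > 0) {
    for (r in seq_len(nrow(structure$pairs))) {
      out[[length(out) + 1L]] <-
        secondary_structure(structure$pairs[-r, , drop = FALSE], n)
    }
  }
  # additions
  prs <- structure$pairs
  for (i in seq_len(n)) {
    if (mate[i] != 0) next
    jmin <- i + .THETA + 1L
    if (jmin > n) break
    for (j in jmin:n) {
      if (mate[j] != 0 || .pair_code(ch[i], ch[j]) == 0L) next
      crossing <- FALSE
      if (nrow(prs) > 0) {
        a_in <- prs[, 1] > i & prs[, 1] < j
        b_in <- prs[, 2] > i & prs[, 2] < j
        crossing <- any(a_in != b_in)
      }
      if (!crossing)
        out[[length(out) + 1L]] <- secondary_structure(rbind(prs, c(i, j)), n)
    }
  }
  out
}

#' Is a structure locally optimal?
#'
#' A structure is locally optimal iff no structure obtained by adding or
#' removing a single base pair has strictly lower free energy (ties do not
#' break optimality). This is the definition-level check by full
#' neighborhood enumeration; it serves as the reference for the dynamic
#' programming engine.
#'
#' @inheritParams structure_energy
#' @return logical.
#' @examples
#' toy <- load_parameters("toy")
#' is_locally_optimal(toy, "GCAAAAGC", "((....))")  # TRUE
#' is_locally_optimal(toy, "GCAAAAGC", "(......)")  # FALSE: removal gains
#' @export
is_locally_optimal <- function(model, seq, structure) {
  sq <- normalize_sequence(seq)
  structure <- as_rna_structure(structure, nchar(sq))
  E0 <- structure_energy(model, sq, structure)
  for (nb in neighbors(sq, structure)) {
    if (structure_energy(model, sq, nb) < E0 - .EPS) return(FALSE)
  }
  TRUE
}

#' Base-pair distance between two structures
#'
#' Size of the symmetric difference of the two pair sets.
#'
#' @param s1,s2 structures (any form accepted by [as_rna_structure()]) on
#'   sequences of the same length.
#' @return a non-negative integer.
#' @export
base_pair_distance <- function(s1, s2) {
  s1 <- as_rna_structure(s1)
  s2 <- as_rna_structure(s2)
  if (s1$n != s2$n)
    stop("structures live on different sequence lengths: ", s1$n, " vs ", s2$n)
  key <- function(s) if (nrow(s$pairs) == 0) character(0)
                     else paste(s$pairs[, 1], s$pairs[, 2])
  k1 <- key(s1); k2 <- key(s2)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}
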