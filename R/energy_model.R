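# Loop-resolved nearest-neighbor free energies at 37 degrees C, without
# dangling ends or coaxial stacking. The total free energy of a structure is
# the sum over its unique loop decomposition of hairpin, internal-loop
# (stacks, bulges, interiors) and affine multiloop terms; the external loop
# contributes only terminal AU/GU penalties.

.PAIR_NAMES <- c("AU", "CG", "GC", "UA", "GU", "UG")
.NUC_CODES <- c(A = 1L, C = 2L, G = 3L, U = 4L)

#' Normalize an RNA sequence string
#'
#' Uppercases, maps T to U and validates the alphabet.
#'
#' @param seq a single character string over A/C/G/U (T accepted).
#' @return the normalized sequence string.
#' @export
normalize_sequence <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L)
    stop("'seq' must be a single character string")
  s <- chartr("t", "u", tolower(seq))
  s <- toupper(s)
  bad <- setdiff(unique(strsplit(s, "")[[1]]), names(.NUC_CODES))
  if (length(bad) > 0)
    stop("invalid nucleotide(s) in sequence: ", paste(bad, collapse = ", "))
  s
}

# integer codes 1..4 for A,C,G,U
encode_sequence <- function(seq) {
  unname(.NUC_CODES[strsplit(normalize_sequence(seq), "")[[1]]])
}

#' Canonical pair type of two nucleotides
#'
#' @param a,b single characters (or the two ends of a putative pair).
#' @return one of `"AU","CG","GC","UA","GU","UG"`, or `NA` if the pair is
#'   not canonical (Watson-Crick or wobble).
#' @export
pair_type <- function(a, b) {
  key <- paste0(toupper(sub("T", "U", a, fixed = TRUE)),
                toupper(sub("T", "U", b, fixed = TRUE)))
  if (key %in% .PAIR_NAMES) key else NA_character_
}

.pair_code <- function(a, b) {
  # integer pair code matching the C++ engine (0 = non-canonical)
  key <- paste0(a, b)
  m <- match(key, .PAIR_NAMES)
  if (is.na(m)) 0L else m
}

.is_augu <- function(pt) pt %in% c(1L, 4L, 5L, 6L)

#' Load a nearest-neighbor energy model
#'
#' Builds an energy model at 37 degrees C from a builtin name or a
#' parameter file in the package's Vienna-style plain-text dialect.
#' The builtin `"toy"` model has flat loop energies (hairpin +2.0, stack
#' -2.0, every other internal loop +1.0, multiloop 3.0/0.1/0.4, RT = 0.6)
#' chosen so that small examples are computable by hand; `"turner"` loads
#' the shipped Turner-style table. Dangle and coaxial-stacking blocks in
#' parameter files are ignored: the model has no dangles.
#'
#' @param source `"toy"`, `"turner"`, or a path to a parameter file.
#' @param temperature temperature in degrees C; only 37 is supported.
#' @return an object of class `rna_energy_model`.
#' @examples
#' toy <- load_parameters("toy")
#' turner <- load_parameters("turner")
#' @export
load_parameters <- function(source = "turner", temperature = 37) {
  if (!isTRUE(all.equal(as.numeric(temperature), 37)))
    stop("parameter error: only 37 C parameters are available, requested ",
         temperature, " C")
  if (identical(source, "toy")) return(.toy_model())
  path <- if (identical(source, "turner")) {
    system.file("extdata", "turner_nn.par", package = "locopt", mustWork = TRUE)
  } else {
    if (!is.character(source) || length(source) != 1L || !file.exists(source))
      stop("parameter error: unreadable parameter source '", source, "'")
    source
  }
  model <- .parse_parameter_file(path)
  model$name <- if (identical(source, "turner")) "turner" else path
  model$RT <- 0.0019872 * 310.15
  structure(model, class = "rna_energy_model")
}

.toy_model <- function() {
  stack <- matrix(-2, 6, 6, dimnames = list(.PAIR_NAMES, .PAIR_NAMES))
  structure(list(
    name = "toy", RT = 0.6,
    theta = .THETA, max_internal = .MAX_INTERNAL,
    hairpin = rep(2, 30), bulge = rep(1, 30), interior = rep(1, 30),
    hairpin_ext = 0, ninio_m = 0, ninio_max = 0,
    stack = stack,
    ml_close = 3, ml_unpaired = 0.1, ml_branch = 0.4,
    au_gu = 0
  ), class = "rna_energy_model")
}

# Parse the package's Vienna-style parameter dialect: sections are headed by
# lines "# <name>"; other "#" lines are comments; INF marks forbidden motifs.
.parse_parameter_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  known <- c("stack", "hairpin", "bulge", "interior", "ML_params",
             "NINIO", "Terminal_AU", "END",
             "dangle5", "dangle3", "coaxial")
  sections <- list()
  current <- NULL
  for (ln in lines) {
    hdr <- regmatches(ln, regexec("^#\\s+(\\S+)\\s*$", ln))[[1]]
    if (length(hdr) == 2 && hdr[2] %in% known) {
      current <- hdr[2]
      sections[[current]] <- character(0)
      next
    }
    if (grepl("^\\s*#", ln) || is.null(current)) next
    sections[[current]] <- c(sections[[current]], ln)
  }
  num <- function(name, n_expected) {
    if (is.null(sections[[name]]))
      stop("parameter error: block '", name, "' missing from ", path)
    toks <- unlist(strsplit(paste(sections[[name]], collapse = " "), "\\s+"))
    toks <- toks[nzchar(toks)]
    vals <- suppressWarnings(ifelse(toks == "INF", Inf, as.numeric(toks)))
    if (anyNA(vals) || length(vals) != n_expected)
      stop("parameter error: block '", name, "' truncated or malformed in ",
           path, " (expected ", n_expected, " values, found ", length(vals), ")")
    vals
  }
  st <- matrix(num("stack", 36), 6, 6, byrow = TRUE,
               dimnames = list(.PAIR_NAMES, .PAIR_NAMES))
  ml <- num("ML_params", 3)
  ninio <- num("NINIO", 2)
  list(
    theta = .THETA, max_internal = .MAX_INTERNAL,
    hairpin = num("hairpin", 30), bulge = num("bulge", 30),
    interior = num("interior", 30),
    hairpin_ext = 1.75 * 0.0019872 * 310.15,
    ninio_m = ninio[1], ninio_max = ninio[2],
    stack = st,
    ml_close = ml[1], ml_unpaired = ml[2], ml_branch = ml[3],
    au_gu = num("Terminal_AU", 1)
  )
}

#' @export
print.rna_energy_model <- function(x, ...) {
  cat("<rna_energy_model> ", x$name, "\n", sep = "")
  cat("  RT = ", format(x$RT, digits = 6), " kcal/mol, theta = ", x$theta,
      ", internal loops <= ", x$max_internal, "\n", sep = "")
  cat("  multiloop a/b/c = ", x$ml_close, "/", x$ml_unpaired, "/",
      x$ml_branch, ", terminal AU/GU = ", x$au_gu, "\n", sep = "")
  invisible(x)
}

.check_pair <- function(codes, i, j, what = "pair") {
  n <- length(codes)
  if (i < 1 || j > n || i >= j)
    stop("invalid indices (", i, ",", j, ") for sequence of length ", n)
  pt <- .pair_code(names(.NUC_CODES)[codes[i]], names(.NUC_CODES)[codes[j]])
  if (pt == 0L)
    stop("non-canonical ", what, " (", i, ",", j, ")")
  pt
}

#' Hairpin loop free energy
#'
#' @param model an [rna_energy_model][load_parameters].
#' @param seq RNA sequence string.
#' @param i,j closing pair indices (1-based, `i < j`), canonical, with at
#'   least `theta` unpaired bases enclosed.
#' @return energy in kcal/mol.
#' @export
hairpin_energy <- function(model, seq, i, j) {
  codes <- encode_sequence(seq)
  pt <- .check_pair(codes, i, j)
  size <- j - i - 1L
  if (size < model$theta)
    stop("hairpin loop of size ", size, " smaller than theta = ", model$theta)
  e <- if (size <= 30) model$hairpin[size]
       else model$hairpin[30] + model$hairpin_ext * log(size / 30)
  if (.is_augu(pt)) e <- e + model$au_gu
  e
}

#' Internal loop free energy (stacks, bulges, interior loops)
#'
#' The stacked-pair case is `k = i + 1, l = j - 1`.
#'
#' @inheritParams hairpin_energy
#' @param k,l inner pair indices, `i < k < l < j`, canonical;
#'   `(k-i-1) + (j-l-1)` must not exceed `model$max_internal`.
#' @return energy in kcal/mol.
#' @export
internal_loop_energy <- function(model, seq, i, j, k, l) {
  codes <- encode_sequence(seq)
  pto <- .check_pair(codes, i, j, "outer pair")
  pti <- .check_pair(codes, k, l, "inner pair")
  if (!(i < k && k < l && l < j))
    stop("inner pair must nest strictly inside the outer pair")
  n1 <- k - i - 1L
  n2 <- j - l - 1L
  if (n1 + n2 > model$max_internal)
    stop("internal loop of size ", n1 + n2, " exceeds cap ", model$max_internal)
  if (n1 == 0 && n2 == 0) return(model$stack[pto, pti])
  au <- model$au_gu * (.is_augu(pto) + .is_augu(pti))
  if (n1 == 0 || n2 == 0) return(model$bulge[n1 + n2] + au)
  model$interior[n1 + n2] + min(model$ninio_max, model$ninio_m * abs(n1 - n2)) + au
}

#' Affine multiloop free energy
#'
#' `a + b * n_unpaired + c * (n_branches + 1)` plus one terminal AU/GU
#' penalty per listed AU/GU pair (closing pair and interior branches).
#'
#' @inheritParams hairpin_energy
#' @param n_branches number of interior branches (>= 2).
#' @param n_unpaired number of unpaired bases in the multiloop.
#' @param closing_and_branch_pairs character vector of pair contexts, e.g.
#'   `c("GC", "AU", "UA")`, closing pair first; used only for the AU/GU
#'   penalty.
#' @return energy in kcal/mol.
#' @export
multiloop_energy <- function(model, n_branches, n_unpaired,
                             closing_and_branch_pairs = character()) {
  if (n_branches < 0 || n_unpaired < 0)
    stop("negative branch or unpaired count")
  au_n <- sum(vapply(closing_and_branch_pairs,
                     function(p) .is_augu(.pair_code(substr(p, 1, 1),
                                                     substr(p, 2, 2))),
                     logical(1)))
  model$ml_close + model$ml_unpaired * n_unpaired +
    model$ml_branch * (n_branches + 1) + model$au_gu * au_n
}

#' Total free energy of a secondary structure
#'
#' Sum of loop free energies over the unique loop decomposition; the
#' external loop contributes only terminal AU/GU penalties.
#'
#' @inheritParams hairpin_energy
#' @param structure an [rna_structure][secondary_structure] or dot-bracket
#'   string.
#' @return energy in kcal/mol.
#' @examples
#' toy <- load_parameters("toy")
#' structure_energy(toy, "GCAAAAGC", "((....))")  # -2 + 2 = 0
#' @export
structure_energy <- function(model, seq, structure) {
  structure <- as_rna_structure(structure, nchar(normalize_sequence(seq)))
  validate_structure(seq, structure)
  loops <- loop_decomposition(structure)
  sq <- normalize_sequence(seq)
  pair_ctx <- function(p) paste0(substr(sq, p[1], p[1]), substr(sq, p[2], p[2]))
  E <- 0
  for (lp in loops) {
    E <- E + switch(lp$kind,
      hairpin = hairpin_energy(model, sq, lp$closing[1], lp$closing[2]),
      internal = internal_loop_energy(model, sq, lp$closing[1], lp$closing[2],
                                      lp$branches[1, 1], lp$branches[1, 2]),
      multiloop = multiloop_energy(
        model, nrow(lp$branches), length(lp$unpaired),
        c(pair_ctx(lp$closing),
          apply(lp$branches, 1, function(b) pair_ctx(b)))),
      external = {
        if (is.null(lp$branches) || nrow(lp$branches) == 0) 0
        else sum(apply(lp$branches, 1, function(b) {
          pt <- .pair_code(substr(sq, b[1], b[1]), substr(sq, b[2], b[2]))
          if (.is_augu(pt)) model$au_gu else 0
        }))
      })
  }
  E
}

# Boltzmann weight of an energy under a model
.boltz <- function(model, E) exp(-E / model$RT)

# plain-list view handed to the C++ engines
.model_list <- function(model) unclass(model)
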