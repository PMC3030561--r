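.samples_to_db <- function(samples) {
  if (is.data.frame(samples)) samples <- samples$structure
  if (!is.character(samples) || length(samples) == 0)
    stop("'samples' must be a nonempty character vector or data frame of structures")
  n <- unique(nchar(samples))
  if (length(n) != 1)
    stop("samples have differing lengths")
  samples
}

# pair frequency matrix and unpaired frequencies from weighted structures
.weighted_pair_freqs <- function(db, w) {
  n <- nchar(db[1])
  w <- w / sum(w)
  p <- matrix(0, n, n)
  q <- numeric(n)
  for (t in seq_along(db)) {
    st <- parse_dot_bracket(db[t])
    if (nrow(st$pairs) > 0)
      p[st$pairs] <- p[st$pairs] + w[t]
    unp <- setdiff(seq_len(n), c(st$pairs))
    q[unp] <- q[unp] + w[t]
  }
  p <- p + t(p)
  list(p = p, q = q)
}

#' Empirical pair and unpaired frequencies from sampled structures
#'
#' `p[i, j]` is the fraction of samples containing pair `(i, j)`;
#' `q[i]` the fraction in which `i` is unpaired. The sum rule
#' `q[i] + sum_j p[i, j] = 1` holds by construction.
#'
#' @param samples a character vector of dot-bracket strings, or a data
#'   frame with a `structure` column (as returned by the samplers).
#' @return a list with the symmetric matrix `p` and the vector `q`.
#' @export
empirical_pair_frequencies <- function(samples) {
  db <- .samples_to_db(samples)
  .weighted_pair_freqs(db, rep(1, length(db)))
}

#' Exact pair frequencies of a finite weighted ensemble
#'
#' Boltzmann-exact analogue of [empirical_pair_frequencies()] for a fully
#' enumerated ensemble (e.g. the oracle's locally optimal set).
#'
#' @param structures character vector of dot-bracket strings.
#' @param energies energies (kcal/mol) of the structures; with `model`
#'   they define Boltzmann weights, otherwise uniform weights are used.
#' @param model the energy model supplying `RT` (required with `energies`).
#' @return a list with `p` and `q`.
#' @export
exact_pair_frequencies <- function(structures, energies = NULL, model = NULL) {
  db <- .samples_to_db(structures)
  w <- if (is.null(energies)) rep(1, length(db))
       else {
         if (is.null(model)) stop("'model' required to weight energies")
         exp(-energies / model$RT)
       }
  .weighted_pair_freqs(db, w)
}

#' Pseudo-entropy of a pair probability matrix
#'
#' `-sum_{i<j} p_ij log(p_ij)` (natural log, with `0 log 0 = 0`). The
#' collection of pair probabilities is not a probability distribution,
#' hence "pseudo"-entropy.
#'
#' @param p symmetric pair probability matrix.
#' @return a nonnegative scalar (nats).
#' @export
pseudo_entropy <- function(p) {
  up <- p[upper.tri(p)]
  up <- up[up > 0]
  -sum(up * log(up))
}

#' Average positional Shannon entropy
#'
#' For each position the partner distribution (all partners j plus
#' "unpaired") is a probability distribution; this returns the mean of its
#' Shannon entropy over positions:
#' `(1/n) sum_i [ -sum_j p_ij log p_ij - q_i log q_i ]`.
#'
#' @param p symmetric pair probability matrix.
#' @param q unpaired probabilities; `q[i] + sum_j p[i, j]` must equal 1.
#' @return a nonnegative scalar (nats).
#' @export
average_entropy <- function(p, q) {
  n <- length(q)
  sums <- rowSums(p) + q
  if (any(abs(sums - 1) > 1e-6))
    stop("sum rule violated: q_i + sum_j p_ij must equal 1 per position")
  h <- vapply(seq_len(n), function(i) {
    v <- c(p[i, ], q[i])
    v <- v[v > 0]
    -sum(v * log(v))
  }, numeric(1))
  mean(h)
}

#' Morgan-Higgs structural diversity
#'
#' `n - sum_i sum_{j in 0..n} p'_ij^2` where `p'_{i0} = q_i` and
#' `p'_{ij} = p_ij`: the expected number of positions at which two
#' independent draws from the ensemble disagree. Zero for a point-mass
#' ensemble.
#'
#' @inheritParams average_entropy
#' @return a nonnegative scalar (positions).
#' @export
morgan_higgs_diversity <- function(p, q) {
  n <- length(q)
  sums <- rowSums(p) + q
  if (any(abs(sums - 1) > 1e-6))
    stop("sum rule violated: q_i + sum_j p_ij must equal 1 per position")
  n - sum(q^2) - sum(p^2)
}

#' Vienna structural diversity
#'
#' Expected base-pair distance between two independent draws from the
#' ensemble; in closed form `2 sum_{i<j} p_ij (1 - p_ij)`.
#'
#' @param p symmetric pair probability matrix.
#' @return a nonnegative scalar (base pairs).
#' @export
vienna_diversity <- function(p) {
  up <- p[upper.tri(p)]
  2 * sum(up * (1 - up))
}

#' Coverage of the partition function by a sample
#'
#' Deduplicates the sample by dot-bracket string and reports the number of
#' distinct structures and the sum of their Boltzmann factors divided by
#' the reference partition function.
#'
#' @param samples sampled structures (data frame from the samplers, or a
#'   character vector; energies are recomputed if absent).
#' @param Zref reference partition function (> 0).
#' @inheritParams structure_energy
#' @return a list with `n_distinct` and `coverage`.
#' @export
coverage_statistics <- function(samples, Zref, model, seq) {
  stopifnot(Zref > 0)
  if (is.data.frame(samples) && !is.null(samples$energy)) {
    db <- samples$structure
    en <- samples$energy
  } else {
    db <- .samples_to_db(samples)
    en <- vapply(db, function(d) structure_energy(model, seq, d), numeric(1))
  }
  keep <- !duplicated(db)
  list(n_distinct = sum(keep),
       coverage = sum(exp(-en[keep] / model$RT)) / Zref)
}

#' Structural diversity report for one sequence
#'
#' Computes the four diversity measures (pseudo-entropy, average entropy,
#' Morgan-Higgs, Vienna) plus distinct-structure count and coverage for the
#' locally optimal ensemble (sampled) and the full Boltzmann ensemble
#' (sampled), one row each. Entropies use natural logarithms.
#'
#' @inheritParams structure_energy
#' @param k samples per ensemble.
#' @param seed optional seed.
#' @param max_tail tail window for the locally optimal engine.
#' @return a data frame with one row per ensemble (`"locopt"`, `"all"`)
#'   and columns `Q`, `avg_entropy`, `d_mh`, `d_v`, `n_distinct`,
#'   `coverage`.
#' @export
diversity_report <- function(model, seq, k = 1000, seed = NULL, max_tail = 10) {
  lo <- sample_locopt(model, seq, k = k, seed = seed, max_tail = max_tail)
  al <- sample_all(model, seq, k = k,
                   seed = if (is.null(seed)) NULL else seed + 1L)
  Zl <- compute_locopt_tables(model, seq, max_tail = max_tail)$Ztot
  Za <- compute_inside(model, seq)$Ztotal
  row_for <- function(s, Zref) {
    f <- empirical_pair_frequencies(s)
    cv <- coverage_statistics(s, Zref, model, seq)
    data.frame(Q = pseudo_entropy(f$p),
               avg_entropy = average_entropy(f$p, f$q),
               d_mh = morgan_higgs_diversity(f$p, f$q),
               d_v = vienna_diversity(f$p),
               n_distinct = cv$n_distinct,
               coverage = cv$coverage)
  }
  out <- rbind(cbind(ensemble = "locopt", row_for(lo, Zl)),
               cbind(ensemble = "all", row_for(al, Za)))
  rownames(out) <- NULL
  out
}
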