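#' Entrywise minimum of two probability sets
#'
#' Combines McCaskill (full ensemble) and locally-optimal pairing
#' probabilities by taking entrywise minima, emphasizing base pairs that
#' occur prominently in both ensembles. The per-position sum rule need not
#' hold for the result; that is expected, not an error.
#'
#' @param p_m,q_m pair matrix and unpaired vector from the full ensemble.
#' @param p_lo,q_lo pair matrix and unpaired vector from the locally
#'   optimal ensemble.
#' @return a list with `p` and `q`, the entrywise minima.
#' @export
combine_min <- function(p_m, q_m, p_lo, q_lo) {
  if (!all(dim(p_m) == dim(p_lo)) || length(q_m) != length(q_lo))
    stop("dimension mismatch between the two probability sets")
  list(p = pmin(p_m, p_lo), q = pmin(q_m, q_lo))
}

#' Maximum expected accuracy structure
#'
#' Finds the secondary structure maximizing
#' `2 * gamma * sum_{(i,j) in S} p_ij + alpha * sum_{i unpaired} q_i`
#' by Nussinov-style interval dynamic programming with traceback. Pairs
#' closer than the hairpin distance are ignored; canonicity is not
#' enforced (probabilities derived from valid ensembles are zero for
#' non-canonical pairs). Tie-breaking is deterministic: leave position `i`
#' unpaired, else take the smallest pairing partner.
#'
#' @param p symmetric matrix of pairing probabilities (or MIN-combined
#'   values; the sum rule is not required).
#' @param q per-position unpaired probabilities.
#' @param gamma nonnegative weight on paired positions.
#' @param alpha nonnegative weight on unpaired positions (default 1).
#' @return a list with `structure` (an [rna_structure][secondary_structure])
#'   and `score`.
#' @export
mea_fold <- function(p, q, gamma = 1, alpha = 1) {
  stopifnot(gamma >= 0, alpha >= 0, nrow(p) == length(q))
  n <- length(q)
  theta <- .THETA
  # M[i, j]: best score on [i, j]; padded so that empty intervals read 0
  M <- matrix(0, n + 2, n + 2)
  if (n >= 1) for (i in seq_len(n)) M[i, i] <- alpha * q[i]
  mget <- function(i, j) if (j < i) 0 else M[i, j]
  for (d in seq_len(n - 1)) {
    for (i in seq_len(n - d)) {
      j <- i + d
      best <- alpha * q[i] + M[i + 1, j]
      if (i + theta + 1 <= j) {
        ks <- (i + theta + 1):j
        cand <- 2 * gamma * p[i, ks] +
          M[cbind(rep(i + 1L, length(ks)), ks - 1L)] +
          M[cbind(ks + 1L, rep(j, length(ks)))]
        best <- max(best, max(cand))
      }
      M[i, j] <- best
    }
  }
  score <- if (n >= 1) M[1, n] else 0
  # deterministic traceback
  pairs <- matrix(integer(0), 0, 2)
  stack <- if (n >= 1) list(c(1L, n)) else list()
  tol <- 1e-9
  while (length(stack) > 0) {
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- iv[1]; j <- iv[2]
    while (i <= j) {
      target <- mget(i, j)
      if (abs(alpha * q[i] + mget(i + 1, j) - target) <= tol) {
        i <- i + 1
        next
      }
      found <- FALSE
      if (i + theta + 1 <= j) {
        for (k in (i + theta + 1):j) {
          v <- 2 * gamma * p[i, k] + mget(i + 1, k - 1) + mget(k + 1, j)
          if (abs(v - target) <= tol) {
            pairs <- rbind(pairs, c(i, k))
            if (k + 1 <= j) stack[[length(stack) + 1]] <- c(k + 1L, as.integer(j))
            j <- k - 1L
            i <- i + 1L
            found <- TRUE
            break
          }
        }
      }
      if (!found) { i <- i + 1 }  # numerical fallback: treat i as unpaired
    }
  }
  list(structure = secondary_structure(pairs, n), score = score)
}

#' Sensitivity and positive predictive value of a prediction
#'
#' Exact base-pair matching (no slippage): a predicted pair counts as
#' correct only when identical to a reference pair. Empty denominators
#' yield `NA` (reported as not applicable and excluded from averages).
#'
#' @param predicted,reference structures (anything accepted by
#'   [as_rna_structure()]) on the same sequence length.
#' @return a list with `sensitivity` (`TP / |reference|`) and `ppv`
#'   (`TP / |predicted|`).
#' @export
sensitivity_ppv <- function(predicted, reference) {
  predicted <- as_rna_structure(predicted)
  reference <- as_rna_structure(reference)
  if (predicted$n != reference$n)
    stop("predicted and reference structures have different lengths")
  key <- function(s) if (nrow(s$pairs) == 0) character(0)
                     else paste(s$pairs[, 1], s$pairs[, 2])
  tp <- length(intersect(key(predicted), key(reference)))
  list(sensitivity = if (nrow(reference$pairs) > 0) tp / nrow(reference$pairs) else NA_real_,
       ppv = if (nrow(predicted$pairs) > 0) tp / nrow(predicted$pairs) else NA_real_)
}

#' MEA prediction from a chosen probability source
#'
#' Convenience wrapper: computes pairing probabilities from the full
#' ensemble (`"mccaskill"`, exact outside recursion), from sampled locally
#' optimal structures (`"lo"`, relative frequencies over `k` samples) or
#' from their entrywise minimum (`"min"`), then folds with [mea_fold()].
#'
#' @inheritParams structure_energy
#' @param mode `"mccaskill"`, `"lo"` or `"min"`.
#' @param gamma weight on paired positions.
#' @param k samples for the locally optimal frequencies.
#' @param seed optional seed for the sampling.
#' @param max_tail tail window for the locally optimal engine.
#' @return as [mea_fold()].
#' @export
mea_predict <- function(model, seq, mode = c("mccaskill", "lo", "min"),
                        gamma = 1, k = 10000, seed = NULL, max_tail = 10) {
  mode <- match.arg(mode)
  pm <- if (mode != "lo") pair_probabilities(model, seq) else NULL
  fl <- if (mode != "mccaskill") {
    empirical_pair_frequencies(
      sample_locopt(model, seq, k = k, seed = seed, max_tail = max_tail))
  } else NULL
  pq <- switch(mode,
    mccaskill = list(p = pm$p, q = pm$q),
    lo = fl,
    min = combine_min(pm$p, pm$q, fl$p, fl$q))
  mea_fold(pq$p, pq$q, gamma = gamma)
}
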