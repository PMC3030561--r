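#' Verify the tail bound for the loaded parameter set
#'
#' The conditional recursions check additions that enclose a single
#' multiloop or external branch only within unpaired tail windows of
#' `max_tail` bases on each side; beyond the window the recursion assumes
#' such an addition can never lower the energy. This function re-verifies
#' that assumption by exhaustive search over all tail contexts: pair-type
#' combinations of the enclosing and enclosed pair and all flank distances
#' `(d_l, d_r)` with `max(d_l, d_r) > max_tail` up to the internal-loop
#' cap. Internal-loop energies in this model depend only on pair types and
#' strand gaps, so the search is exact.
#'
#' @param model an energy model.
#' @param max_tail the tail window in use.
#' @param max_total optionally bound `d_l + d_r` (the largest flank sum a
#'   multiloop stretch can reach at the sequence lengths of interest);
#'   default unbounded up to the internal-loop cap.
#' @return a list with `ok` (logical per context: `external`, `multiloop`),
#'   `worst` (minimum delta observed per context) and `violations` (data
#'   frame of violating contexts, if any).
#' @export
verify_tail_bound <- function(model, max_tail = 10, max_total = Inf) {
  ml <- .model_list(model)
  au <- function(pt) if (.is_augu(pt)) model$au_gu else 0
  rows <- list()
  worst <- c(external = Inf, multiloop = Inf)
  for (dl in 1:(model$max_internal + 1)) {
    for (dr in 1:(model$max_internal + 1)) {
      if (max(dl, dr) <= max_tail) next
      if (dl + dr > max_total) next
      n1 <- dl - 1; n2 <- dr - 1
      if (n1 + n2 > model$max_internal) next
      for (pt_out in 1:6) {
        for (pt_in in 1:6) {
          el <- cpp_el_generic(ml, pt_out, pt_in, n1, n2)
          if (el > 1e8) next
          base <- el + au(pt_out) - au(pt_in)
          d_ext <- base
          d_ml <- base - model$ml_unpaired * (dl + dr)
          worst["external"] <- min(worst["external"], d_ext)
          worst["multiloop"] <- min(worst["multiloop"], d_ml)
          if (d_ext < -.EPS || d_ml < -.EPS) {
            rows[[length(rows) + 1]] <- data.frame(
              d_l = dl, d_r = dr,
              outer = .PAIR_NAMES[pt_out], inner = .PAIR_NAMES[pt_in],
              delta_external = d_ext, delta_multiloop = d_ml)
          }
        }
      }
    }
  }
  viol <- if (length(rows) > 0) do.call(rbind, rows)
          else data.frame()
  list(ok = c(external = unname(worst["external"]) >= -.EPS,
              multiloop = unname(worst["multiloop"]) >= -.EPS),
       worst = worst, violations = viol)
}

#' Search for energy-lowering multiloop-splitting additions
#'
#' The recursions assume that a single base pair enclosing two or more
#' branches of a multiloop (splitting it into two multiloops), or two or
#' more external branches (creating a new multiloop), can never lower the
#' energy. This randomized guard samples structures from the full
#' Boltzmann ensemble of random sequences, enumerates every such addition,
#' and evaluates its energy change by full loop decomposition.
#'
#' @param model an energy model.
#' @param n sequence length for the random contexts.
#' @param n_seq number of random sequences.
#' @param k samples per sequence.
#' @param seed RNG seed.
#' @return a list with `n_candidates` (splitting additions examined),
#'   `min_delta` (smallest energy change; `Inf` when none found) and `ok`.
#' @export
verify_multiloop_split <- function(model, n = 50, n_seq = 5, k = 40,
                                   seed = 1L) {
  # designed contexts guarantee candidates exist: a three-branch multiloop
  # with a splitting G-C addition, and two external branches that a G-C
  # addition would wrap into a new multiloop
  contexts <- list(
    list(seq = "GGGGAAACCAGGAAACCCGGAAACCAC",
         db = "(.((...)).((...)).((...)).)"),
    list(seq = "GGGAAACCAGGAAACCC",
         db = ".((...)).((...))."))
  .with_seed(seed, {
    for (sq in random_sequences(n, n_seq)) {
      for (db in unique(sample_all(model, sq, k = k)$structure))
        contexts[[length(contexts) + 1L]] <- list(seq = sq, db = db)
    }
    min_delta <- Inf
    n_cand <- 0L
    for (ctx in contexts) {
      sq <- ctx$seq
      st <- parse_dot_bracket(ctx$db)
      E0 <- structure_energy(model, sq, st)
      ch <- strsplit(sq, "")[[1]]
      for (lp in loop_decomposition(st)) {
        if (!(lp$kind %in% c("multiloop", "external"))) next
        nb <- nrow(lp$branches)
        if (nb < 2) next
        unp <- lp$unpaired
        for (x in unp) for (y in unp[unp > x + .THETA]) {
          if (.pair_code(ch[x], ch[y]) == 0L) next
          enclosed <- sum(lp$branches[, 1] > x & lp$branches[, 2] < y)
          # splitting additions: >= 2 enclosed, and for multiloops at
          # least one branch left outside
          if (enclosed < 2) next
          if (lp$kind == "multiloop" && enclosed == nb) next
          st2 <- secondary_structure(rbind(st$pairs, c(x, y)), st$n)
          dE <- structure_energy(model, sq, st2) - E0
          n_cand <- n_cand + 1L
          min_delta <- min(min_delta, dE)
        }
      }
    }
    list(n_candidates = n_cand, min_delta = min_delta,
         ok = min_delta >= -.EPS)
  })
}

#' Verify that only internal loops enter multiloops and external loops
#'
#' The recursions restrict multiloop and external branches to components
#' whose top pair borders an internal loop below: removing a branch pair
#' that directly closes a hairpin or a multiloop is assumed to always
#' lower the energy. This checks the assumption in closed form over the
#' model's tables, for hairpin sizes realizable up to `n_max`.
#'
#' @param model an energy model.
#' @param n_max largest sequence length of interest.
#' @return a list with `ok` and the worst margins per case.
#' @export
verify_branch_assumption <- function(model, n_max = 80) {
  au_min <- 0
  au_max <- model$au_gu
  eh_of <- function(s) {
    vapply(s, function(x) {
      if (x <= 30) model$hairpin[x]
      else model$hairpin[30] + model$hairpin_ext * log(x / 30)
    }, numeric(1))
  }
  # hairpin branch in external loop: removal gains -(EH + au) < 0 <=> EH + au > 0
  sizes <- .THETA:max(.THETA, n_max - 2)
  ext_hp <- min(eh_of(sizes)) + au_min
  # hairpin branch in a multiloop: removal delta = b*(s+2) - c - EH - au < 0.
  # A multiloop needs its closing pair and a second branch of width >= theta+2,
  # so the hairpin loop size is at most n_max - 9.
  sizes_ml <- .THETA:max(.THETA, n_max - 9)
  ml_hp <- min(model$ml_branch + eh_of(sizes_ml) + au_min -
                 model$ml_unpaired * (sizes_ml + 2))
  # multiloop directly under a multiloop branch: delta = -a + 2b - 2c - 2 au < 0
  ml_ml <- model$ml_close - 2 * model$ml_unpaired + 2 * model$ml_branch + 2 * au_min
  # multiloop directly under an external branch: delta = -(a + b u + c(h+1)) - 2 au
  ext_ml <- model$ml_close + 3 * model$ml_branch + 2 * au_min
  margins <- c(external_hairpin = ext_hp, multiloop_hairpin = ml_hp,
               multiloop_multiloop = ml_ml, external_multiloop = ext_ml)
  list(ok = all(margins > .EPS), margins = margins, au_max = au_max)
}
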