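#' Random RNA sequences
#'
#' I.i.d. uniform nucleotides (0th-order Markov chain with probability 1/4
#' for each of A, C, G, U).
#'
#' @param length sequence length (>= 1).
#' @param count number of sequences (>= 1).
#' @param seed optional seed; the same seed reproduces the list.
#' @return a character vector of sequences.
#' @export
random_sequences <- function(length, count, seed = NULL) {
  stopifnot(length >= 1, count >= 1)
  .with_seed(seed, {
    vapply(seq_len(count), function(i) {
      paste(sample(c("A", "C", "G", "U"), length, replace = TRUE),
            collapse = "")
    }, character(1))
  })
}

#' Least-squares fit of exponential growth
#'
#' Ordinary least squares of `log10(mean count)` against sequence length;
#' `r_squared` is the squared Pearson correlation of the fit.
#'
#' @param lengths sequence lengths (>= 3 distinct values).
#' @param mean_log10_counts `log10` of the mean structure counts at each
#'   length.
#' @return a list with `slope`, `intercept` and `r_squared`.
#' @export
growth_fit <- function(lengths, mean_log10_counts) {
  if (length(lengths) < 3)
    stop("at least 3 points required for a growth fit")
  if (length(unique(lengths)) < 2)
    stop("degenerate x-values: lengths must vary")
  fit <- stats::lm(mean_log10_counts ~ lengths)
  r2 <- if (stats::sd(mean_log10_counts) == 0) NA_real_
        else unname(stats::cor(lengths, mean_log10_counts)^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2)
}

#' Growth of structure counts with sequence length
#'
#' For each length, generates random sequences, counts all and locally
#' optimal structures by dynamic programming, and fits `log10(mean count)`
#' against length for both ensembles. The ratio of the two slopes is about
#' 2 when the number of all structures is approximately the square of the
#' number of locally optimal ones.
#'
#' @param lengths vector of sequence lengths.
#' @param reps random sequences per length.
#' @param seed RNG seed.
#' @param model energy model (local optimality is evaluated at its
#'   energies even though counting removes the Boltzmann weights).
#' @param max_tail tail window.
#' @return a list with the per-length `table` (mean log10 counts), the
#'   two fits (`fit_all`, `fit_locopt`) and `slope_ratio`.
#' @export
growth_experiment <- function(lengths = c(20, 40, 60, 80), reps = 20,
                              seed = 1L, model = load_parameters("turner"),
                              max_tail = 10) {
  rows <- lapply(seq_along(lengths), function(t) {
    n <- lengths[t]
    seqs <- random_sequences(n, reps, seed = seed + t)
    ca <- vapply(seqs, function(s) count_structures(model, s, "all"), numeric(1))
    cl <- vapply(seqs, function(s)
      count_structures(model, s, "locopt", max_tail = max_tail), numeric(1))
    data.frame(length = n,
               mean_log10_all = log10(mean(ca)),
               mean_log10_locopt = log10(mean(cl)))
  })
  tab <- do.call(rbind, rows)
  fit_all <- growth_fit(tab$length, tab$mean_log10_all)
  fit_lo <- growth_fit(tab$length, tab$mean_log10_locopt)
  list(table = tab, fit_all = fit_all, fit_locopt = fit_lo,
       slope_ratio = fit_all$slope / fit_lo$slope)
}

#' Boltzmann weight of local optima as a function of length
#'
#' For each length, generates random sequences and computes the ratio
#' `Ztot / Z` of the locally optimal to the full partition function: the
#' percentage of the Boltzmann ensemble, by weight, that is locally
#' optimal. Also fits an exponential decay `c * r^n` through the means.
#'
#' @inheritParams growth_experiment
#' @return a list with `table` (columns `length`, `mean_ratio`, `stderr`)
#'   and `fit` (`c`, `r`, `r_squared` of the log-linear fit).
#' @export
ratio_experiment <- function(lengths = c(20, 40, 60, 80), reps = 20,
                             seed = 1L, model = load_parameters("turner"),
                             max_tail = 10) {
  rows <- lapply(seq_along(lengths), function(t) {
    n <- lengths[t]
    seqs <- random_sequences(n, reps, seed = seed + 1000L + t)
    r <- vapply(seqs, function(s)
      locopt_partition_function(model, s, max_tail = max_tail)$ratio,
      numeric(1))
    data.frame(length = n, mean_ratio = mean(r),
               stderr = stats::sd(r) / sqrt(length(r)))
  })
  tab <- do.call(rbind, rows)
  lf <- stats::lm(log(tab$mean_ratio) ~ tab$length)
  fit <- list(c = exp(unname(stats::coef(lf)[1])),
              r = exp(unname(stats::coef(lf)[2])),
              r_squared = unname(stats::cor(tab$length, log(tab$mean_ratio))^2))
  list(table = tab, fit = fit)
}

#' Sampling coverage of the two ensembles
#'
#' For each length, samples `k_samples` structures per random sequence from
#' the full Boltzmann ensemble and from the locally optimal subensemble,
#' and reports the mean and standard deviation of the number of distinct
#' structures and of the coverage (Boltzmann weight of the distinct sample
#' divided by the respective partition function).
#'
#' @inheritParams growth_experiment
#' @param k_samples samples per sequence and ensemble.
#' @return a data frame with one row per length.
#' @export
coverage_experiment <- function(lengths = 60, reps = 10, k_samples = 1000,
                                seed = 1L, model = load_parameters("turner"),
                                max_tail = 10) {
  rows <- lapply(seq_along(lengths), function(t) {
    n <- lengths[t]
    seqs <- random_sequences(n, reps, seed = seed + 2000L + t)
    st <- lapply(seq_along(seqs), function(u) {
      s <- seqs[u]
      Za <- compute_inside(model, s)$Ztotal
      Zl <- compute_locopt_tables(model, s, max_tail = max_tail)$Ztot
      sa <- sample_all(model, s, k = k_samples, seed = seed + 10L * u)
      sl <- sample_locopt(model, s, k = k_samples, seed = seed + 10L * u + 1L,
                          max_tail = max_tail)
      ca <- coverage_statistics(sa, Za, model, s)
      cl <- coverage_statistics(sl, Zl, model, s)
      c(da = ca$n_distinct, dl = cl$n_distinct,
        cva = ca$coverage, cvl = cl$coverage)
    })
    m <- do.call(rbind, st)
    data.frame(length = n,
               mean_distinct_all = mean(m[, "da"]), sd_distinct_all = stats::sd(m[, "da"]),
               mean_distinct_locopt = mean(m[, "dl"]), sd_distinct_locopt = stats::sd(m[, "dl"]),
               mean_coverage_all = mean(m[, "cva"]), sd_coverage_all = stats::sd(m[, "cva"]),
               mean_coverage_locopt = mean(m[, "cvl"]), sd_coverage_locopt = stats::sd(m[, "cvl"]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
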