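#' Exact enumeration of a stratified SRSWOR design
#'
#' Visits every possible stratified SRSWOR sample of a small population
#' exactly once (each with probability `1 / prod(choose(N_i, n_i))`),
#' evaluates a statistic on each, and returns the full design distribution
#' with its exact mean and variance. This is the ground-truth surface
#' against which the estimators' design moments (unbiasedness of the HT
#' total, the collapsed-stratum bias identity, the kernel expectation
#' functional) are verified numerically.
#'
#' @param population A `strat_pop` tibble.
#' @param n Per-stratum SRSWOR sizes (scalar or vector).
#' @param statistic Function of a `strat_sample` tibble returning a scalar;
#'   default the HT total.
#' @param max_outcomes Hard cap on `prod(choose(N_i, n_i))`; exceeding it is
#'   an error, never silent subsampling.
#' @return An object of class `fs_design_dist`: list with `value` and `prob`
#'   vectors (one entry per sample), `mean`, `var` and `n_outcomes`.
#' @examples
#' pop <- stratified_population(data.frame(stratum = 1, x = 1, y = 1:3))
#' d <- enumerate_design(pop, n = 1)
#' d$mean  # 6: the true total
#' d$var   # 6
#' @export
enumerate_design <- function(population, n, statistic = ht_total,
                             max_outcomes = 1e6) {
  population <- stratified_population(population)
  strata <- pop_strata(population)
  H <- nrow(strata)
  n <- check_sample_sizes(n, strata)
  n_out <- prod(choose(strata$N, n))
  if (n_out > max_outcomes) {
    abort(sprintf("enumeration too large: %g samples exceeds the cap of %g",
                  n_out, max_outcomes),
          class = "finestrat_too_large")
  }
  idx_by_stratum <- split(seq_len(nrow(population)),
                          factor(population$stratum, levels = strata$stratum))
  combos <- lapply(seq_len(H), function(i) {
    combn(idx_by_stratum[[i]], n[i], simplify = FALSE)
  })
  grid <- as.matrix(do.call(expand.grid, lapply(combos, seq_along)))
  pi_by_stratum <- n / strata$N
  base <- as.data.frame(population[, c("stratum", "x", "xu", "y")])
  Nmap <- setNames(strata$N, strata$stratum)
  pimap <- setNames(pi_by_stratum, strata$stratum)
  values <- vapply(seq_len(nrow(grid)), function(r) {
    rows <- unlist(lapply(seq_len(H), function(i) combos[[i]][[grid[r, i]]]))
    s <- base[rows, ]
    s$N <- Nmap[as.character(s$stratum)]
    s$pi <- pimap[as.character(s$stratum)]
    s <- tibble::as_tibble(s)
    class(s) <- c("strat_sample", class(s))
    statistic(s)
  }, numeric(1))
  probs <- rep(1 / n_out, n_out)
  new_design_dist(values, probs)
}

new_design_dist <- function(values, probs) {
  m <- sum(values * probs)
  v <- sum((values - m)^2 * probs)
  structure(list(value = values, prob = probs, mean = m, var = v,
                 n_outcomes = length(values)),
            class = "fs_design_dist")
}

#' @export
print.fs_design_dist <- function(x, ...) {
  cat("<fs_design_dist> ", x$n_outcomes, " outcomes, mean ", format(x$mean),
      ", var ", format(x$var), "\n", sep = "")
  invisible(x)
}

#' @rdname enumerate_design
#' @param x An `fs_design_dist`.
#' @param ... Unused.
#' @return `tidy()` on a design distribution returns the support aggregated
#'   over equal values, with total probability per value.
#' @export
tidy.fs_design_dist <- function(x, ...) {
  tb <- tibble::tibble(value = x$value, prob = x$prob)
  dplyr::summarise(dplyr::group_by(tb, .data$value),
                   prob = sum(.data$prob), .groups = "drop") |>
    dplyr::arrange(.data$value)
}

#' Exact resampling law of a bootstrap replicate total
#'
#' Enumerates all `m^nstar` equally likely ordered with-replacement draws
#' from the HT contributions `z` of one pseudo-stratum and returns the exact
#' distribution of the replicate total `t* = (m/nstar) * sum(z_draws)`. Its
#' mean equals `sum(z)` exactly, which is what makes the exact-law bias
#' corrector vanish.
#'
#' @param z Numeric vector of HT contributions in the pseudo-stratum.
#' @param nstar Resample size.
#' @param max_outcomes Cap on `m^nstar`.
#' @return An `fs_design_dist` over replicate totals.
#' @examples
#' tidy(exact_bootstrap_law(c(4, 6), 2))  # totals 8, 10, 12 with probs 1/4, 1/2, 1/4
#' @export
exact_bootstrap_law <- function(z, nstar, max_outcomes = 1e6) {
  m <- length(z)
  n_out <- m^nstar
  if (n_out > max_outcomes) {
    abort(sprintf("enumeration too large: %g ordered draws exceeds the cap of %g",
                  n_out, max_outcomes),
          class = "finestrat_too_large")
  }
  grid <- as.matrix(do.call(expand.grid, rep(list(seq_len(m)), nstar)))
  totals <- (m / nstar) * rowSums(matrix(z[grid], nrow = n_out))
  new_design_dist(totals, rep(1 / n_out, n_out))
}
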