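#' Construct a stratified finite population
#'
#' A stratified population is a tibble with one row per population unit and
#' columns `stratum` (stratum label), `x` (a stratum-level auxiliary score,
#' constant within stratum, used to order strata and to place kernel
#' windows), and `y` (the study variable). An optional column `xu` carries a
#' unit-level auxiliary score; when absent it defaults to the stratum score.
#' Strata are sorted by `x` (ties broken by stratum label) and the result is
#' the ground truth that the sampling, estimation and enumeration functions
#' consume.
#'
#' @param data A data frame with columns `stratum`, `x`, `y` and optionally
#'   `xu`.
#' @return A tibble of class `strat_pop`, ordered by `x` then `stratum`.
#' @examples
#' pop <- stratified_population(
#'   data.frame(stratum = rep(1:2, each = 3), x = rep(c(.5, 1), each = 3),
#'              y = c(1, 2, 3, 4, 5, 6))
#' )
#' pop_strata(pop)
#' @export
stratified_population <- function(data) {
  required <- c("stratum", "x", "y")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("population is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "finestrat_schema_error")
  }
  if (!is.numeric(data$x) || !is.numeric(data$y)) {
    abort("columns `x` and `y` must be numeric",
          class = "finestrat_parse_error")
  }
  if (anyNA(data$y) || anyNA(data$x)) {
    abort("`x` and `y` must not contain missing values",
          class = "finestrat_parse_error")
  }
  out <- tibble::as_tibble(data)
  if (!"xu" %in% names(out)) out$xu <- out$x
  # one score per stratum
  chk <- dplyr::summarise(dplyr::group_by(out, .data$stratum),
                          nx = dplyr::n_distinct(.data$x), .groups = "drop")
  if (any(chk$nx != 1)) {
    abort("stratum score `x` must be constant within each stratum",
          class = "finestrat_consistency_error")
  }
  out <- dplyr::arrange(out, .data$x, .data$stratum)
  class(out) <- c("strat_pop", class(out))
  out
}

#' Per-stratum summary of a population
#'
#' @param population A `strat_pop` tibble (see [stratified_population()]).
#' @return A tibble with one row per stratum: `stratum`, `x`, `N` (stratum
#'   size) and `t` (true stratum total), in stratum order.
#' @export
pop_strata <- function(population) {
  population <- stratified_population(population)
  dplyr::summarise(dplyr::group_by(population, .data$stratum),
                   x = .data$x[1], N = dplyr::n(), t = sum(.data$y),
                   .groups = "drop") |>
    dplyr::arrange(.data$x, .data$stratum)
}

#' Draw a stratified SRSWOR sample
#'
#' Draws a simple random sample without replacement of size `n_i` from every
#' stratum independently and records the inclusion probabilities
#' `pi = n_i / N_i`.
#'
#' @param population A `strat_pop` tibble.
#' @param n Per-stratum sample size: a single integer recycled to all strata,
#'   or a vector with one entry per stratum in stratum order.
#' @param seed Optional integer seed; the same seed reproduces the same
#'   sample.
#' @return A tibble of class `strat_sample` with columns `stratum`, `N`, `x`,
#'   `xu`, `y`, `pi`, one row per sampled unit, in stratum order.
#' @export
draw_srswor <- function(population, n = 2, seed = NULL) {
  population <- stratified_population(population)
  strata <- pop_strata(population)
  H <- nrow(strata)
  n <- check_sample_sizes(n, strata)
  if (!is.null(seed)) set.seed(seed)
  idx_by_stratum <- split(seq_len(nrow(population)),
                          factor(population$stratum, levels = strata$stratum))
  rows <- unlist(lapply(seq_len(H), function(i) {
    idx <- idx_by_stratum[[i]]
    idx[sample.int(length(idx), n[i])]
  }))
  out <- population[rows, c("stratum", "x", "xu", "y")]
  out <- dplyr::left_join(out, strata[, c("stratum", "N")], by = "stratum")
  out$pi <- n[match(out$stratum, strata$stratum)] / out$N
  out <- out[, c("stratum", "N", "x", "xu", "y", "pi")]
  class(out) <- c("strat_sample", class(out))
  out
}

check_sample_sizes <- function(n, strata) {
  H <- nrow(strata)
  if (length(n) == 1) n <- rep(n, H)
  if (length(n) != H) {
    abort("`n` must have length 1 or one entry per stratum",
          class = "finestrat_config_error")
  }
  if (any(n < 1)) {
    abort("per-stratum sample sizes must be >= 1",
          class = "finestrat_infeasible_design")
  }
  if (any(n > strata$N)) {
    abort("per-stratum sample size exceeds stratum size N_i",
          class = "finestrat_infeasible_design")
  }
  as.integer(n)
}

#' Validate a stratified sample tibble
#'
#' Accepts any data frame with columns `stratum`, `N`, `x`, `y`, `pi`
#' (and optionally `xu`), checks the design is usable (all `pi` in (0, 1]),
#' and returns it ordered by stratum score.
#'
#' @param data A data frame of sampled units.
#' @return A `strat_sample` tibble.
#' @export
as_strat_sample <- function(data) {
  if (inherits(data, "strat_sample")) return(data)
  required <- c("stratum", "N", "x", "y", "pi")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("sample is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "finestrat_schema_error")
  }
  if (anyNA(data$pi) || any(data$pi <= 0) || any(data$pi > 1)) {
    abort("inclusion probabilities `pi` must lie in (0, 1] and be non-missing",
          class = "finestrat_invalid_design")
  }
  out <- tibble::as_tibble(data)
  if (!"xu" %in% names(out)) out$xu <- out$x
  out <- dplyr::arrange(out, .data$x, .data$stratum)
  class(out) <- c("strat_sample", class(out))
  out
}

#' Horvitz-Thompson stratum totals
#'
#' Computes the per-stratum Horvitz-Thompson estimates
#' `t_hat_i = sum(y_k / pi_k)` over sampled units, whose sum estimates the
#' population total without bias under any measurable fixed-probability
#' design.
#'
#' @param sample A `strat_sample` tibble (or a data frame coercible via
#'   [as_strat_sample()]).
#' @return A tibble with one row per stratum: `stratum`, `x`, `N`, `n`
#'   (realised sample size) and `that` (the HT stratum total), with the
#'   overall estimate available as `sum(result$that)` or via [ht_total()].
#' @examples
#' s <- tibble::tibble(stratum = 1, N = 4, x = 1, y = c(1, 3), pi = 0.5)
#' ht_totals(s)$that  # 8
#' @export
ht_totals <- function(sample) {
  sample <- as_strat_sample(sample)
  # rows arrive in stratum-score order; rowsum keeps it (first appearance)
  f <- factor(sample$stratum, levels = unique(sample$stratum))
  i1 <- !duplicated(f)
  tibble::tibble(stratum = sample$stratum[i1], x = sample$x[i1],
                 N = sample$N[i1], n = tabulate(f),
                 that = as.numeric(rowsum(sample$y / sample$pi, f)))
}

#' @rdname ht_totals
#' @return `ht_total()` returns the scalar estimate of the population total.
#' @export
ht_total <- function(sample) sum(ht_totals(sample)$that)

#' True design variance of the HT total under stratified SRSWOR
#'
#' For SRSWOR of `n_i` units from a stratum of `N_i` with unit variance
#' `S_i^2` (denominator `N_i - 1`), the design variance of the HT stratum
#' total is `V_i = N_i^2 (1 - n_i/N_i) S_i^2 / n_i`. The total variance is
#' the sum over strata because strata are sampled independently. The closed
#' form is valid down to `n_i = 1`, where it reduces to
#' `N_i * sum(y^2) - t_i^2`.
#'
#' @param population A `strat_pop` tibble.
#' @param n Per-stratum SRSWOR sample sizes (scalar or vector, as in
#'   [draw_srswor()]).
#' @return A tibble with one row per stratum (`stratum`, `x`, `N`, `n`,
#'   `Vi`); the total design variance is `sum(result$Vi)`.
#' @export
true_variance <- function(population, n = 2) {
  population <- stratified_population(population)
  strata <- pop_strata(population)
  n <- check_sample_sizes(n, strata)
  s2 <- dplyr::summarise(dplyr::group_by(population, .data$stratum),
                         S2 = if (dplyr::n() > 1) var(.data$y) else 0,
                         .groups = "drop")
  out <- dplyr::left_join(strata, s2, by = "stratum")
  out$n <- n[match(out$stratum, strata$stratum)]
  out$Vi <- out$N^2 * (1 - out$n / out$N) * out$S2 / out$n
  out[, c("stratum", "x", "N", "n", "Vi")]
}

# Deterministic substream seeds: one root seed per run, a distinct stream per
# purpose and index, all below 2^31 so set.seed() accepts them anywhere.
derive_seed <- function(root, index = 0L, stream = "sampling") {
  offset <- c(population = 11L, sampling = 29L, bootstrap = 47L,
              simulation = 71L)[[stream]]
  as.integer((as.double(root) + 10007 * index + 97 * offset) %% 2147483629)
}
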