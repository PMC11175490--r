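#' Read a stratified sample from CSV
#'
#' Expects a header row with columns `stratum,N_i,x_i,y` and optionally
#' `pi`; one row per sampled unit. When `pi` is absent it defaults to
#' `n_i / N_i` computed from the per-stratum row counts (the SRSWOR value).
#' Strata are re-sorted by `x_i` regardless of file order.
#'
#' @param path Path to the CSV file.
#' @return A `strat_sample` tibble.
#' @export
read_sample_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_guess()))
  required <- c("stratum", "N_i", "x_i", "y")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("sample CSV is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "finestrat_schema_error")
  }
  if (!is.numeric(raw$y)) {
    bad <- which(is.na(suppressWarnings(as.numeric(raw$y))))
    abort(paste0("non-numeric `y` at data row(s): ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "finestrat_parse_error")
  }
  chk <- dplyr::summarise(dplyr::group_by(raw, .data$stratum),
                          nN = dplyr::n_distinct(.data$N_i),
                          .groups = "drop")
  if (any(chk$nN != 1)) {
    abort("`N_i` must be constant within each stratum",
          class = "finestrat_consistency_error")
  }
  out <- dplyr::rename(raw, N = "N_i", x = "x_i")
  if (!"pi" %in% names(out)) {
    out <- dplyr::mutate(dplyr::group_by(out, .data$stratum),
                         pi = dplyr::n() / .data$N)
    out <- dplyr::ungroup(out)
  }
  as_strat_sample(out)
}

#' @rdname read_sample_csv
#' @param sample A `strat_sample` tibble.
#' @return `write_sample_csv()` writes the file (columns
#'   `stratum,N_i,x_i,y,pi`) and returns `path` invisibly; a write-then-read
#'   round trip preserves all fields.
#' @export
write_sample_csv <- function(sample, path) {
  sample <- as_strat_sample(sample)
  out <- tibble::tibble(stratum = sample$stratum, N_i = sample$N,
                        x_i = sample$x, y = sample$y, pi = sample$pi)
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a stratified population from CSV
#'
#' Columns `stratum,x_i,y`, one row per population unit; `N_i` is inferred
#' from the per-stratum row counts.
#'
#' @param path Path to the CSV file.
#' @return A `strat_pop` tibble.
#' @export
read_population_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("stratum", "x_i", "y")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("population CSV is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "finestrat_schema_error")
  }
  stratified_population(dplyr::rename(raw, x = "x_i"))
}

#' Prepare a mental-health-organisations style survey frame
#'
#' Applies the preprocessing used in the worked application on the 1998
#' survey of mental health organisations (user-supplied; the data ship with
#' survey-practice packages as `smho98` and are not bundled here): drop
#' organisations with zero inpatient beds, collapse the stratum pairs
#' {12,13}, {10,11}, {6,8} and {4,5} (small cells after the exclusion),
#' drop strata emptied by the filter, and order the remaining strata by the
#' log of their total bed count, which becomes the stratum score.
#'
#' @param data A data frame with columns `stratum` (numeric stratum codes),
#'   `beds` (inpatient beds) and the study variable named by `y` (default
#'   `"exp_total"`, total expenditures).
#' @param y Name of the study-variable column.
#' @return A `strat_pop` tibble whose `y` is the study variable and whose
#'   `x` is the log total beds of the (possibly merged) stratum.
#' @export
smho_prepare <- function(data, y = "exp_total") {
  required <- c("stratum", "beds", y)
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "finestrat_schema_error")
  }
  keep <- data$beds > 0
  if (!any(keep)) {
    abort("no organisations left after dropping zero-bed rows",
          class = "finestrat_empty_after_filter")
  }
  df <- data[keep, ]
  merges <- list(c(12, 13), c(10, 11), c(6, 8), c(4, 5))
  stratum <- as.character(df$stratum)
  for (pair in merges) {
    stratum[stratum %in% as.character(pair)] <-
      paste(pair, collapse = "+")
  }
  df$stratum <- stratum
  score <- dplyr::summarise(dplyr::group_by(df, .data$stratum),
                            x = log(sum(.data$beds)), .groups = "drop")
  df <- dplyr::left_join(df[, c("stratum", y)], score, by = "stratum")
  names(df)[names(df) == y] <- "y"
  stratified_population(df)
}

#' Repeated-subsample study on a prepared survey frame
#'
#' Draws `reps` independent SRSWOR samples of `n` units per stratum from a
#' prepared frame (e.g. [smho_prepare()]), runs the three variance
#' estimators on each, and summarises per estimator: the mean estimate, its
#' coefficient of variation across subsamples (sd/mean), the bias against
#' the true design variance, and the RMSE.
#'
#' @param population A `strat_pop` tibble.
#' @param n SRSWOR size per stratum (default 2).
#' @param reps Number of repeated subsamples (default 200).
#' @param B,nstar,mode Bootstrap settings (see [estimate_bootstrap()]).
#' @param h Kernel bandwidth; default `1.5 / H` after rescaling scores to
#'   span `[0, 1]`.
#' @param seed Root seed; the report is reproducible under a fixed seed.
#' @return A tibble with one row per estimator: `estimator`, `mean`, `cv`,
#'   `bias`, `rmse`, plus the true variance as an attribute `true_var`.
#' @export
smho_study <- function(population, n = 2, reps = 200, B = 200, nstar = 2,
                       mode = "resample", h = NULL, seed = 1) {
  population <- stratified_population(population)
  # scores rescaled to [0, 1] so the bandwidth heuristics carry over
  rng <- range(population$x)
  if (diff(rng) > 0) {
    population$x <- (population$x - rng[1]) / diff(rng)
    population$xu <- (population$xu - rng[1]) / diff(rng)
  }
  population <- stratified_population(population)
  strata <- pop_strata(population)
  H <- nrow(strata)
  if (is.null(h)) h <- 1.5 / H
  V <- sum(true_variance(population, n)$Vi)
  plan <- make_pairing(strata)
  W <- kernel_weights(strata$x, h)
  vals <- purrr::map(seq_len(reps), function(r) {
    s <- draw_srswor(population, n, seed = derive_seed(seed, r, "sampling"))
    tt <- ht_totals(s)
    tibble::tibble(
      replicate = r,
      estimator = c("collapsed", "kernel", "bootstrap"),
      value = c(v_collapsed(tt$that, plan)$value,
                v_kernel(tt$that, W)$value,
                estimate_bootstrap(s, B = B, nstar = nstar, mode = mode,
                                   seed = derive_seed(seed, r,
                                                      "bootstrap"))$value))
  })
  long <- dplyr::bind_rows(vals)
  out <- dplyr::summarise(dplyr::group_by(long, .data$estimator),
                          mean = mean(.data$value),
                          cv = sd(.data$value) / mean(.data$value),
                          bias = mean(.data$value) - V,
                          rmse = sqrt(mean((.data$value - V)^2)),
                          .groups = "drop")
  attr(out, "true_var") <- V
  out
}
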