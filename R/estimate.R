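#' Variance-estimate objects
#'
#' All variance estimators in the package return an `fs_estimate`: the
#' numeric estimate together with the estimator id, the normalising constant
#' used (where the estimator has one) and a diagnostics list (collapsing
#' plan, weights, corrector mode, warnings). Use [tidy()] to get a one-row
#' tibble.
#'
#' @param value Numeric estimate.
#' @param estimator Estimator id, e.g. `"collapsed"`.
#' @param c_const Normalising constant (`NA` when not applicable).
#' @param diagnostics Named list of estimator-specific details.
#' @return An object of class `fs_estimate`.
#' @keywords internal
#' @export
fs_estimate <- function(value, estimator, c_const = NA_real_,
                        diagnostics = list()) {
  structure(list(value = value, estimator = estimator, c_const = c_const,
                 diagnostics = diagnostics),
            class = "fs_estimate")
}

#' @export
print.fs_estimate <- function(x, ...) {
  cat("<fs_estimate> ", x$estimator, ": ", format(x$value), sep = "")
  if (!is.na(x$c_const)) cat("  (normalising constant ", format(x$c_const), ")",
                             sep = "")
  cat("\n")
  invisible(x)
}

#' @rdname fs_estimate
#' @param x An `fs_estimate`.
#' @param ... Unused.
#' @export
tidy.fs_estimate <- function(x, ...) {
  tibble::tibble(estimator = x$estimator, value = x$value,
                 c_const = x$c_const,
                 note = x$diagnostics$note %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Estimate the variance of the HT total from a stratified sample
#'
#' One-call front end running any or all of the three fine-stratification
#' variance estimators on a sample: the collapsed-stratum estimator on
#' adjacent pairs in `x`-order, the Epanechnikov kernel-weighted estimator,
#' and the pseudo-stratum bootstrap estimator.
#'
#' @param sample A `strat_sample` tibble (see [as_strat_sample()],
#'   [read_sample_csv()]).
#' @param estimator `"all"` or a subset of `"collapsed"`, `"kernel"`,
#'   `"bootstrap"`.
#' @param h Kernel bandwidth on the scale of the stratum scores; default
#'   `1.5 / H`, inside the smallest non-empty window `(1/H, 2/H)` for the
#'   grid `x_i = i/H`.
#' @param B,nstar,mode,n_pseudo Bootstrap settings, see
#'   [estimate_bootstrap()].
#' @param seed Integer seed for the bootstrap resampling.
#' @return A tibble with one row per estimator: `estimator`, `value`,
#'   `c_const`, `H`, `note`.
#' @examples
#' pop <- make_population(sim_config(N = 200, H = 10, sigma = 0.25, seed = 7))
#' s <- draw_srswor(pop, n = 2, seed = 1)
#' estimate_variance(s, B = 100, seed = 2)
#' @export
estimate_variance <- function(sample,
                              estimator = c("all", "collapsed", "kernel",
                                            "bootstrap"),
                              h = NULL, B = 1000, nstar = 2,
                              mode = "resample", n_pseudo = NULL,
                              seed = NULL) {
  estimator <- match.arg(estimator, several.ok = TRUE)
  if ("all" %in% estimator) estimator <- c("collapsed", "kernel", "bootstrap")
  sample <- as_strat_sample(sample)
  tt <- ht_totals(sample)
  H <- nrow(tt)
  out <- list()
  if ("collapsed" %in% estimator) {
    plan <- make_pairing(tt)
    out$collapsed <- tidy(v_collapsed(tt$that, plan))
  }
  if ("kernel" %in% estimator) {
    if (is.null(h)) h <- 1.5 / H
    W <- kernel_weights(tt$x, h)
    out$kernel <- tidy(v_kernel(tt$that, W))
  }
  if ("bootstrap" %in% estimator) {
    out$bootstrap <- tidy(estimate_bootstrap(sample, B = B, nstar = nstar,
                                             mode = mode, n_pseudo = n_pseudo,
                                             seed = seed))
  }
  res <- dplyr::bind_rows(out)
  res$H <- H
  res[, c("estimator", "value", "c_const", "H", "note")]
}
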