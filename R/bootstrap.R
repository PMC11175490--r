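#' Bootstrap replicate totals over pseudo-strata
#'
#' For each pseudo-stratum `j` holding `m_j` Horvitz-Thompson contributions
#' `z_k = y_k / pi_k`, draws `nstar` of the `z` with replacement (equal
#' probability) `B` times and forms the replicate total
#' `t*_bj = (m_j / nstar) * sum(z_draws)`, so the exact resampling
#' expectation of every replicate total is the pseudo-stratum HT total
#' `t_bj = sum_k z_k`.
#'
#' @param psample A sample tibble with a `pseudo` column (from
#'   [collapse_singletons()] or [pseudo_strata()]).
#' @param B Number of resamples.
#' @param nstar Resample size per pseudo-stratum (default 2).
#' @param seed Optional integer seed.
#' @return A `B x J` matrix of replicate totals with attributes `t_b`
#'   (pseudo-stratum HT totals), `m` (pseudo-stratum unit counts), `fpc`
#'   (sampling fractions `m_j / N_j`) and `nstar`.
#' @export
bootstrap_replicates <- function(psample, B, nstar = 2, seed = NULL) {
  stopifnot("pseudo" %in% names(psample), B >= 1, nstar >= 1)
  if (!is.null(seed)) set.seed(seed)
  ord <- order(psample$x, psample$stratum)
  psample <- psample[ord, ]
  groups <- split(seq_len(nrow(psample)),
                  factor(psample$pseudo, levels = unique(psample$pseudo)))
  J <- length(groups)
  reps <- matrix(0, B, J, dimnames = list(NULL, names(groups)))
  t_b <- numeric(J)
  m <- integer(J)
  fpc <- numeric(J)
  z_all <- psample$y / psample$pi
  for (j in seq_len(J)) {
    idx <- groups[[j]]
    z <- z_all[idx]
    m[j] <- length(z)
    t_b[j] <- sum(z)
    # pseudo-stratum population size: sum of N_i over distinct merged strata
    fpc[j] <- m[j] / sum(psample$N[idx][!duplicated(psample$stratum[idx])])
    draws <- matrix(z[sample.int(m[j], B * nstar, replace = TRUE)], B, nstar)
    reps[, j] <- (m[j] / nstar) * rowSums(draws)
  }
  structure(reps, t_b = t_b, m = m, fpc = fpc, nstar = nstar)
}

#' Form pseudo-strata for resampling
#'
#' Thin wrapper around [collapse_singletons()] that can additionally coarsen
#' the pseudo-strata: with `n_pseudo` set, strata are grouped in score order
#' into `n_pseudo` nearly equal blocks before resampling (a knob for designs
#' whose collapsing convention calls for a fixed number of pseudo-strata).
#'
#' @param sample A `strat_sample` tibble.
#' @param n_pseudo Optional number of pseudo-strata; `NULL` (default) merges
#'   singleton strata only.
#' @return As [collapse_singletons()].
#' @export
pseudo_strata <- function(sample, n_pseudo = NULL) {
  sample <- as_strat_sample(sample)
  if (is.null(n_pseudo)) return(collapse_singletons(sample))
  info <- dplyr::summarise(dplyr::group_by(sample, .data$stratum),
                           x = .data$x[1], n = dplyr::n(), .groups = "drop")
  info <- dplyr::arrange(info, .data$x, .data$stratum)
  H <- nrow(info)
  if (n_pseudo < 1 || n_pseudo > H) {
    abort("`n_pseudo` must be between 1 and the number of strata",
          class = "finestrat_config_error")
  }
  block <- ceiling(seq_len(H) / (H / n_pseudo))
  plan <- tibble::tibble(stratum = info$stratum,
                         pseudo = sprintf("P%03d", block), n = info$n)
  out <- dplyr::left_join(sample, plan[, c("stratum", "pseudo")],
                          by = "stratum")
  class(out) <- class(sample)
  list(sample = out, plan = plan,
       merges = tibble::tibble(singleton = character(),
                               partner = character()))
}

#' Bootstrap bias corrector
#'
#' The Monte-Carlo bias estimate of a pseudo-stratum total is
#' `Bias_B(t_bj) = mean_b(t*_bj) - t_bj`; the corrector is
#' `a_bj = t_bj - Bias_B(t_bj) = 2 t_bj - mean_b(t*_bj)`. Because the
#' resampling scheme is exactly unbiased for `t_bj`, the corrector equals
#' `t_bj` under the exact resampling law and deviates only by Monte-Carlo
#' noise of order `B^{-1/2}`. In `"sum_to_one"` mode the correctors are
#' additionally normalised to unit sum so they can stand in the weight slot
#' of the kernel-form estimator.
#'
#' @param replicates Replicate matrix from [bootstrap_replicates()] (or any
#'   `B x J` matrix).
#' @param t_b Pseudo-stratum totals; defaults to the matrix attribute.
#' @param mode `"sum_to_one"` (default) or `"raw"`.
#' @return A list with `bias_B`, `a` (correctors) and `w` (the weights:
#'   normalised correctors in `"sum_to_one"` mode, the raw correctors
#'   otherwise).
#' @export
bias_corrector <- function(replicates, t_b = attr(replicates, "t_b"),
                           mode = c("sum_to_one", "raw")) {
  mode <- match.arg(mode)
  stopifnot(!is.null(t_b), ncol(replicates) == length(t_b))
  bias_B <- colMeans(replicates) - t_b
  a <- t_b - bias_B
  if (mode == "sum_to_one") {
    if (abs(sum(a)) < 1e-12) {
      abort("degenerate corrector: bootstrap bias correctors sum to zero",
            class = "finestrat_degenerate_corrector")
    }
    w <- a / sum(a)
  } else {
    w <- a
  }
  list(bias_B = bias_B, a = a, w = w, mode = mode)
}

#' Corrector-weight bootstrap variance estimator
#'
#' The kernel-form estimator with the bootstrap bias correctors in the
#' weight slot:
#' `V_boot = (1/c_b) * sum_i (t_bi - sum_j w_j t_bj)^2`, with the
#' normalising constant `c_b = (1/J) sum_i (1 - 2 w_i + sum_j w_j^2)` built
#' from the corrector weights in strict analogy with the kernel constant. A
#' zero `c_b` is an error; a negative `c_b` (possible for raw,
#' total-scaled correctors) is reported with a warning and flagged in the
#' diagnostics rather than silently sign-flipped.
#'
#' @param t_b Pseudo-stratum HT totals.
#' @param w Corrector weights from [bias_corrector()] (the `w` element, or
#'   the whole list).
#' @param c_b Optional override of the normalising constant.
#' @return An [fs_estimate()] carrying `c_b` and the weights.
#' @examples
#' v_bootstrap(c(10, 30), c(0.25, 0.75))$value  # 400
#' @export
v_bootstrap <- function(t_b, w, c_b = NULL) {
  if (is.list(w) && !is.null(w$w)) w <- w$w
  stopifnot(length(w) == length(t_b))
  J <- length(t_b)
  if (is.null(c_b)) c_b <- mean(1 - 2 * w + sum(w^2))
  if (abs(c_b) < 1e-12) {
    abort("degenerate normaliser: c_b = 0",
          class = "finestrat_degenerate_normalizer")
  }
  note <- NA_character_
  if (c_b < 0) {
    warn("normalising constant c_b is negative; estimate sign preserved")
    note <- "negative c_b"
  }
  center <- sum(w * t_b)
  value <- sum((t_b - center)^2) / c_b
  fs_estimate(value, "bootstrap_corrector", c_const = c_b,
              diagnostics = list(w = w, note = note))
}

#' Resampling-variability bootstrap variance estimator
#'
#' Estimates each pseudo-stratum's variance contribution from the
#' Monte-Carlo variability of its replicate totals around their exact
#' expectation, rescaled for the finite-population sampling fraction and the
#' resample size:
#' `V_boot = sum_j g_j * (1/B) sum_b (t*_bj - t_bj)^2` with
#' `g_j = nstar * (1 - f_j) / (m_j - 1)`. The rescale makes the estimator
#' exactly design-unbiased for the SRSWOR stratum variance when the
#' pseudo-strata are intact strata (`m_j = n_j`), in the spirit of the
#' rescaling bootstrap for stratified designs; the total is the sum over
#' pseudo-strata because resampling is independent across them.
#'
#' @param replicates Replicate matrix from [bootstrap_replicates()] (must
#'   carry its `t_b`, `m`, `fpc`, `nstar` attributes, or supply them).
#' @param t_b,m,fpc,nstar Overrides for the matrix attributes.
#' @return An [fs_estimate()] with per-pseudo-stratum contributions in the
#'   diagnostics.
#' @export
v_bootstrap_resample <- function(replicates, t_b = attr(replicates, "t_b"),
                                 m = attr(replicates, "m"),
                                 fpc = attr(replicates, "fpc"),
                                 nstar = attr(replicates, "nstar")) {
  stopifnot(!is.null(t_b), !is.null(m), !is.null(fpc), !is.null(nstar))
  if (any(m < 2)) {
    abort("every pseudo-stratum needs at least 2 units; merge singletons first",
          class = "finestrat_cannot_bootstrap")
  }
  mc_var <- colMeans(sweep(replicates, 2, t_b)^2)
  g <- nstar * (1 - fpc) / (m - 1)
  vj <- g * mc_var
  fs_estimate(sum(vj), "bootstrap", c_const = NA_real_,
              diagnostics = list(vj = vj, rescale = g))
}

#' Bootstrap variance estimation pipeline
#'
#' Runs the full bootstrap estimator on a stratified sample: merge
#' single-unit strata into pseudo-strata, draw `B` resamples of size `nstar`
#' per pseudo-stratum, and form the variance estimate. `mode = "resample"`
#' (default) uses the resampling-variability estimator
#' ([v_bootstrap_resample()]); `"corrector"` and `"corrector_raw"` use the
#' corrector-weight form ([v_bootstrap()]) with sum-to-one or raw
#' correctors.
#'
#' @param sample A `strat_sample` tibble.
#' @param B Number of resamples (default 1000).
#' @param nstar Resample size per pseudo-stratum (default 2).
#' @param mode `"resample"`, `"corrector"` or `"corrector_raw"`.
#' @param n_pseudo Optional fixed number of pseudo-strata (see
#'   [pseudo_strata()]).
#' @param seed Optional integer seed for the resampling.
#' @return An [fs_estimate()]; diagnostics include the pseudo-stratum plan,
#'   merge log, mode and seed.
#' @export
estimate_bootstrap <- function(sample, B = 1000, nstar = 2,
                               mode = c("resample", "corrector",
                                        "corrector_raw"),
                               n_pseudo = NULL, seed = NULL) {
  mode <- match.arg(mode)
  ps <- pseudo_strata(sample, n_pseudo = n_pseudo)
  reps <- bootstrap_replicates(ps$sample, B = B, nstar = nstar, seed = seed)
  est <- switch(mode,
    resample = v_bootstrap_resample(reps),
    corrector = v_bootstrap(attr(reps, "t_b"),
                            bias_corrector(reps, mode = "sum_to_one")),
    corrector_raw = v_bootstrap(attr(reps, "t_b"),
                                bias_corrector(reps, mode = "raw"))
  )
  est$estimator <- "bootstrap"
  est$diagnostics <- c(est$diagnostics,
                       list(plan = ps$plan, merges = ps$merges, mode = mode,
                            B = B, nstar = nstar, seed = seed))
  est
}
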