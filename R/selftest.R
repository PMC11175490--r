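#' Run the exact-identity self-test suite
#'
#' Re-derives the package's design-moment identities on small built-in
#' populations by brute-force enumeration and reports each check with its
#' tolerance: HT unbiasedness, the collapsed-stratum bias identity, the
#' kernel expectation functional (homoscedastic strata), the binary-weight
#' equivalence of the kernel and collapsed estimators, and the exactness of
#' the bootstrap resampling law. Intended as a quick integrity check of an
#' installation (`finestrat selftest` from the CLI).
#'
#' @param seed Seed for the randomised checks.
#' @return A tibble with columns `check`, `discrepancy`, `tol`, `pass`.
#' @export
fs_selftest <- function(seed = 1) {
  set.seed(seed)
  checks <- list()
  add <- function(check, discrepancy, tol) {
    checks[[length(checks) + 1]] <<-
      tibble::tibble(check = check, discrepancy = discrepancy, tol = tol,
                     pass = discrepancy <= tol)
  }

  pop <- stratified_population(tibble::tibble(
    stratum = rep(sprintf("S%d", 1:4), times = c(3, 3, 4, 4)),
    x = rep(c(0.25, 0.5, 0.75, 1), times = c(3, 3, 4, 4)),
    y = c(1, 2, 3, 2, 3, 4, 1, 1, 2, 3, 2, 2, 4, 5)))
  strata <- pop_strata(pop)
  t_true <- strata$t

  d <- enumerate_design(pop, n = 1)
  add("HT total is design-unbiased (enumerated E[t_hat] = t)",
      abs(d$mean - sum(t_true)), 1e-10)

  tv <- true_variance(pop, n = 1)
  add("enumerated var(t_hat) matches closed-form stratum variances",
      abs(d$var - sum(tv$Vi)), 1e-10)

  plan <- make_pairing(strata)
  dcol <- enumerate_design(pop, n = 1,
                           statistic = function(s)
                             v_collapsed(ht_totals(s)$that, plan)$value)
  add("collapsed-estimator bias identity (E[V_col] - var = closed form)",
      abs((dcol$mean - d$var) - collapsed_bias_exact(t_true, plan)), 1e-10)

  pop2 <- stratified_population(tibble::tibble(
    stratum = rep(sprintf("S%d", 1:4), each = 3),
    x = rep(1:4 / 4, each = 3),
    y = c(1, 2, 3, 2, 3, 4, 3, 4, 5, 4, 5, 6)))  # equal spread: constant V_i
  st2 <- pop_strata(pop2)
  W <- suppressWarnings(kernel_weights(st2$x, h = 0.3))
  dker <- enumerate_design(pop2, n = 1,
                           statistic = function(s)
                             v_kernel(ht_totals(s)$that, W)$value)
  ex <- kernel_expectation_exact(st2$t, true_variance(pop2, 1), W)
  add("kernel expectation functional matches enumeration (constant V_i)",
      abs(dker$mean - ex$expectation), 1e-10)

  that <- rnorm(6, 10, 3)
  plan6 <- make_pairing(tibble::tibble(stratum = 1:6, x = 1:6))
  Wpair <- as_kernel_weights(collapse_matrix(plan6))
  add("binary pair weights make the kernel estimator the collapsed one",
      abs(v_kernel(that, Wpair)$value - v_collapsed(that, plan6)$value) /
        max(v_collapsed(that, plan6)$value, 1e-12), 1e-12)

  z <- c(4, 6, 7)
  law <- exact_bootstrap_law(z, nstar = 2)
  add("exact bootstrap law is unbiased for the pseudo-stratum total",
      abs(law$mean - sum(z)), 1e-12)

  dplyr::bind_rows(checks)
}
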