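make_psample <- function(z_by_pseudo, N_each = 10) {
  # build a minimal pseudo-sample carrying HT contributions z directly (pi = 1)
  purrr::imap_dfr(z_by_pseudo, function(z, nm) {
    tibble::tibble(stratum = paste0(nm, "_", seq_along(z)), N = N_each,
                   x = match(nm, names(z_by_pseudo)) + seq_along(z) / 100,
                   y = z, pi = 1, pseudo = nm)
  })
}

test_that("replicate totals are exactly centred on the pseudo-stratum total", {
  law <- exact_bootstrap_law(c(4, 6), nstar = 2)
  expect_equal(law$mean, 10)
  expect_equal(tidy(law)$value, c(8, 10, 12))
  expect_equal(tidy(law)$prob, c(0.25, 0.5, 0.25))

  # constant contributions: degenerate replicate law
  ps <- make_psample(list(A = c(5, 5, 5)))
  reps <- bootstrap_replicates(ps, B = 50, nstar = 2, seed = 1)
  expect_true(all(reps == 15))
})

test_that("Monte-Carlo replicate means obey the law of large numbers", {
  z <- c(4, 6, 11)
  ps <- make_psample(list(A = z))
  B <- 2e4
  reps <- bootstrap_replicates(ps, B = B, nstar = 2, seed = 42)
  law <- exact_bootstrap_law(z, nstar = 2)
  se <- sqrt(law$var / B)
  expect_lt(abs(mean(reps) - sum(z)), 3 * se)
})

test_that("the bias corrector is null under the exact law and for constant z", {
  # exact law as a replicate matrix: one row per equally likely outcome
  z <- c(4, 6)
  law <- exact_bootstrap_law(z, nstar = 2)
  reps <- matrix(law$value, ncol = 1)
  bc <- bias_corrector(reps, t_b = sum(z), mode = "raw")
  expect_equal(bc$bias_B, 0)
  expect_equal(bc$a, sum(z))

  ps <- make_psample(list(A = c(3, 3)))
  reps2 <- bootstrap_replicates(ps, B = 30, nstar = 2, seed = 2)
  bc2 <- bias_corrector(reps2, mode = "raw")
  expect_equal(unname(bc2$bias_B), 0)
})

test_that("sum-to-one correctors normalise as stated and detect degeneracy", {
  reps <- matrix(rep(c(10, 30), each = 4), ncol = 2)  # replicates == totals
  bc <- bias_corrector(reps, t_b = c(10, 30), mode = "sum_to_one")
  expect_equal(bc$w, c(0.25, 0.75))
  expect_error(
    bias_corrector(matrix(c(5, -5), 1), t_b = c(5, -5), mode = "sum_to_one"),
    class = "finestrat_degenerate_corrector")
})

test_that("the corrector-weight estimator reproduces hand arithmetic", {
  est <- v_bootstrap(c(10, 30), c(0.25, 0.75))
  expect_equal(est$value, 400)
  expect_equal(est$c_const, 0.625)
  expect_equal(v_bootstrap(c(7, 7), c(0.5, 0.5))$value, 0)
  expect_error(v_bootstrap(10, 1), class = "finestrat_degenerate_normalizer")
  expect_warning(v_bootstrap(c(10, 30), c(0.25, 0.75), c_b = -0.5),
                 "negative")
})

test_that("Monte-Carlo corrector bias shrinks like B^{-1/2}", {
  z <- c(2, 9, 5)
  ps <- make_psample(list(A = z))
  set.seed(9)
  dev_for <- function(B) {
    abs(mean(replicate(40, {
      reps <- bootstrap_replicates(ps, B = B, nstar = 2)
      bias_corrector(reps, mode = "raw")$bias_B
    })^2))
  }
  # mean squared Monte-Carlo bias scales ~ 1/B (allow 2x slack)
  expect_lt(dev_for(1600), dev_for(100) / 16 * 2)
})

test_that("the resampling estimator is exact on the enumerated replicate law", {
  z <- c(4, 6)
  m <- 2; nstar <- 2; fpc <- 2 / 10
  law <- exact_bootstrap_law(z, nstar)
  reps <- matrix(rep(law$value, round(law$prob * 4)), ncol = 1)  # 4 outcomes
  est <- v_bootstrap_resample(reps, t_b = sum(z), m = m, fpc = fpc,
                              nstar = nstar)
  # exact resampling variance (z1-z2)^2/2 = 2, rescaled by n*(1-f)/(m-1)
  expect_equal(est$value, 2 * (1 - fpc) * 2)
  # matches the textbook unbiased SRSWOR stratum variance estimator:
  # N^2 (1 - n/N) s^2 / n with y = z * n/N
  y <- z * m / 10
  expect_equal(est$value, 10^2 * (1 - fpc) * var(y) / m)
})

test_that("the full bootstrap pipeline is reproducible and scale-equivariant", {
  pop <- toy_pop(rep(list(c(1, 5, 3, 8)), 6))
  s <- draw_srswor(pop, 2, seed = 4)
  e1 <- estimate_bootstrap(s, B = 200, seed = 11)
  e2 <- estimate_bootstrap(s, B = 200, seed = 11)
  expect_equal(e1$value, e2$value)

  for (mode in c("resample", "corrector")) {
    for (a in c(0.5, 3)) {
      sa <- s
      sa$y <- a * sa$y
      va <- estimate_bootstrap(sa, B = 150, mode = mode, seed = 7)$value
      v1 <- estimate_bootstrap(s, B = 150, mode = mode, seed = 7)$value
      expect_equal(va, a^2 * v1, tolerance = 1e-9)
    }
  }
})

test_that("the resampling estimator is nearly design-unbiased at n_i = 2", {
  pop <- toy_pop_const_var(6, base = c(0, 2, 5, 9), shifts = 1:6)
  V <- sum(true_variance(pop, 2)$Vi)
  set.seed(31)
  vals <- purrr::map_dbl(1:150, function(r) {
    s <- draw_srswor(pop, 2)
    estimate_bootstrap(s, B = 150)$value
  })
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - V), 4 * se)
})
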