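test_that("HT stratum totals recover the truth under a census design", {
  pop <- toy_pop(list(c(1, 2, 3), c(4, 5), c(2, 2, 6)))
  strata <- pop_strata(pop)
  tt <- ht_totals(census_sample(pop))
  expect_equal(tt$that, strata$t)
  expect_equal(ht_total(census_sample(pop)), sum(pop$y))
})

test_that("HT totals inverse-weight the sampled units", {
  s <- tibble::tibble(stratum = "A", N = 4, x = 1, y = c(1, 3), pi = 0.5)
  tt <- ht_totals(s)
  expect_equal(tt$that, 8)
  expect_equal(tt$n, 2)
})

test_that("nonpositive or missing inclusion probabilities are rejected", {
  s <- tibble::tibble(stratum = "A", N = 4, x = 1, y = c(1, 3), pi = c(0.5, 0))
  expect_error(ht_totals(s), class = "finestrat_invalid_design")
  s$pi <- c(0.5, NA)
  expect_error(ht_totals(s), class = "finestrat_invalid_design")
  expect_error(as_strat_sample(tibble::tibble(stratum = 1, x = 1, y = 1)),
               class = "finestrat_schema_error")
})

test_that("the HT total is design-unbiased over the enumerated design", {
  pop <- toy_pop(list(c(1, 5, 2), c(7, 1, 4, 3)))
  d <- enumerate_design(pop, n = c(2, 2))
  expect_equal(d$mean, sum(pop$y), tolerance = 1e-12)
})

test_that("SRSWOR draws are feasible, exhaustive at n = N, and reproducible", {
  pop <- toy_pop(list(c(1, 2, 3), c(4, 5)))
  full <- draw_srswor(pop, n = c(3, 2), seed = 1)
  expect_equal(sort(full$y), sort(pop$y))
  expect_equal(unique(full$pi), 1)

  s1 <- draw_srswor(pop, n = 1, seed = 99)
  s2 <- draw_srswor(pop, n = 1, seed = 99)
  expect_identical(s1, s2)

  expect_error(draw_srswor(pop, n = c(4, 1)),
               class = "finestrat_infeasible_design")
  expect_error(draw_srswor(pop, n = 0),
               class = "finestrat_infeasible_design")
})

test_that("empirical selection frequencies match n_i / N_i", {
  pop <- toy_pop(list(c(10, 20, 30, 40), c(1, 2, 3)))
  n_draw <- 3000
  set.seed(7)
  hits <- numeric(nrow(pop))
  for (r in seq_len(n_draw)) {
    s <- draw_srswor(pop, n = c(2, 1))
    hits <- hits + pop$y %in% s$y
  }
  p <- rep(c(2 / 4, 1 / 3), c(4, 3))
  se <- sqrt(p * (1 - p) / n_draw)
  expect_true(all(abs(hits / n_draw - p) < 3 * se))
})

test_that("true_variance matches enumeration and hand cases", {
  # constant y within stratum
  pop0 <- toy_pop(list(c(5, 5, 5)))
  expect_equal(true_variance(pop0, 1)$Vi, 0)

  # y = (1,2,3), n = 1: t_hat in {3,6,9} equally likely -> variance 6
  pop1 <- toy_pop(list(c(1, 2, 3)))
  expect_equal(true_variance(pop1, 1)$Vi, 6)
  expect_equal(enumerate_design(pop1, 1)$var, 6, tolerance = 1e-12)

  # closed form equals the enumerated design variance, n_i = 2, N_i <= 6
  pop <- toy_pop(list(c(1, 4, 2, 6), c(3, 3, 8, 1, 5), c(2, 9, 4, 4, 1, 7)))
  d <- enumerate_design(pop, n = 2)
  expect_equal(d$var, sum(true_variance(pop, 2)$Vi), tolerance = 1e-10)
})

test_that("design variance is additive over independently sampled strata", {
  pop <- toy_pop(list(c(1, 3, 7), c(2, 8, 5, 1)))
  d <- enumerate_design(pop, n = c(1, 2))
  tv <- true_variance(pop, n = c(1, 2))
  expect_equal(d$var, sum(tv$Vi), tolerance = 1e-10)
})

test_that("totals and variances are scale-equivariant in y", {
  pop <- toy_pop(list(c(1, 3, 7), c(2, 8, 5, 1)))
  pop_a <- pop
  pop_a$y <- 3 * pop_a$y
  pop_a <- stratified_population(pop_a)
  expect_equal(true_variance(pop_a, 2)$Vi, 9 * true_variance(pop, 2)$Vi)
  s <- draw_srswor(pop, 2, seed = 5)
  s_a <- s
  s_a$y <- 3 * s_a$y
  expect_equal(ht_totals(s_a)$that, 3 * ht_totals(s)$that)
})

test_that("stratum scores must be constant within stratum and strata sorted", {
  expect_error(
    stratified_population(tibble::tibble(stratum = c(1, 1), x = c(1, 2),
                                         y = c(1, 2))),
    class = "finestrat_consistency_error")
  pop <- stratified_population(tibble::tibble(
    stratum = c("b", "b", "a", "a"), x = c(0.2, 0.2, 0.9, 0.9), y = 1:4))
  expect_equal(pop_strata(pop)$stratum, c("b", "a"))  # ordered by x, not label
})
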