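test_that("every mean shape rescales to range [0, 2] on a dense grid", {
  grid <- seq(0, 1, length.out = 100001)
  for (id in mean_function_ids()) {
    mu_star <- rescale_mean(mean_function(id))
    vals <- mu_star(grid)
    expect_equal(min(vals), 0, tolerance = 1e-6)
    expect_equal(max(vals), 2, tolerance = 1e-6)
  }
  # linear standardises to exactly 2x
  expect_equal(rescale_mean(mean_function("linear"))(c(0, 0.25, 1)),
               c(0, 0.5, 2), tolerance = 1e-9)
  expect_error(rescale_mean(function(x) rep(3, length(x))),
               class = "finestrat_undefined_rescale")
})

test_that("synthetic populations have the stated structure", {
  cfg <- sim_config(N = 300, H = 30, sigma = 0, mean_fn = "quadratic",
                    seed = 5)
  pop <- make_population(cfg)
  strata <- pop_strata(pop)
  expect_equal(nrow(strata), 30)
  expect_equal(unique(strata$N), 10)
  expect_equal(strata$x, 1:30 / 30)
  # noiseless: every unit equals mu*(x_i), totals are (N/H) mu*(x_i)
  mu_star <- rescale_mean(mean_function("quadratic"))
  expect_equal(pop$y, mu_star(pop$x))
  expect_equal(strata$t, 10 * mu_star(strata$x))
  # unit scores fall in their stratum interval
  expect_true(all(pop$xu > pop$x - 1 / 30 & pop$xu <= pop$x))

  expect_error(sim_config(N = 100, H = 30),
               class = "finestrat_config_error")
})

test_that("population noise is standard normal at scale sigma", {
  cfg <- sim_config(N = 3000, H = 100, sigma = 0.25, mean_fn = "linear",
                    seed = 8)
  pop <- make_population(cfg)
  mu_star <- rescale_mean(mean_function("linear"))
  e <- (pop$y - mu_star(pop$x)) / 0.25
  expect_lt(abs(mean(e)), 3 / sqrt(3000))
  expect_lt(abs(var(e) - 1), 3 * sqrt(2 / 2999))
})

test_that("a single replicate gives RMSE equal to absolute bias", {
  cfg <- sim_config(N = 100, H = 10, sigma = 0.25, R = 1, B = 50,
                    estimators = c("collapsed", "kernel"), seed = 2)
  sim <- run_unconditional(cfg)
  expect_equal(sim$summary$rmse, abs(sim$summary$bias))
})

test_that("replicate streams extend: doubling R keeps the first R unchanged", {
  base <- list(N = 100, H = 10, sigma = 0.25, B = 40, seed = 33)
  s5 <- run_unconditional(do.call(sim_config, c(base, list(R = 5))))
  s10 <- run_unconditional(do.call(sim_config, c(base, list(R = 10))))
  first5 <- dplyr::filter(s10$replicates, replicate <= 5)
  expect_equal(first5, s5$replicates)
})

test_that("noiseless runs hit the collapsed closed-form bias exactly", {
  cfg <- sim_config(N = 200, H = 20, sigma = 0, R = 5, B = 40, seed = 3)
  sim <- run_unconditional(cfg)
  expect_equal(sim$true_var, 0)
  pop <- make_population(cfg)
  strata <- pop_strata(pop)
  eq_bias <- collapsed_bias_exact(strata$t, make_pairing(strata))
  col <- dplyr::filter(sim$summary, estimator == "collapsed")
  expect_equal(col$bias, eq_bias, tolerance = 1e-10)
  expect_equal(col$rmse, eq_bias, tolerance = 1e-10)  # no sampling variation
  # kernel bias likewise equals its closed-form bias term
  ker <- dplyr::filter(sim$summary, estimator == "kernel")
  W <- kernel_weights(strata$x, cfg$h)
  expect_equal(ker$bias,
               kernel_expectation_exact(strata$t, rep(0, 20), W)$bias,
               tolerance = 1e-10)
})

test_that("summary metrics satisfy RMSE >= |bias| and CV >= 0", {
  cfg <- sim_config(N = 200, H = 10, sigma = 0.5, R = 40, B = 40,
                    mean_fn = "cycle4", seed = 12)
  sim <- run_unconditional(cfg)
  expect_true(all(sim$summary$rmse >= abs(sim$summary$bias) - 1e-12))
  expect_true(all(sim$summary$cv >= 0))
})

test_that("conditional grouping partitions ordered samples evenly", {
  cfg <- sim_config(N = 200, H = 10, sigma = 0.25, R = 60, B = 30,
                    group_size = 20, estimators = c("collapsed", "kernel"),
                    seed = 14)
  cond <- run_conditional(cfg)
  per_est <- dplyr::filter(cond$groups, estimator == "collapsed")
  expect_equal(nrow(per_est), 3)                    # 60 / 20 groups
  expect_true(all(diff(per_est$xbar) >= 0))         # ordered by x-bar
  # equally weighted pool of conditional biases = unconditional bias
  pooled <- dplyr::summarise(dplyr::group_by(cond$groups, estimator),
                             bias = mean(cond_bias), .groups = "drop")
  expect_equal(dplyr::arrange(pooled, estimator)$bias,
               dplyr::arrange(cond$summary, estimator)$bias,
               tolerance = 1e-10)

  bad <- sim_config(N = 200, H = 10, R = 55, group_size = 20)
  expect_error(run_conditional(bad), class = "finestrat_config_error")
})

test_that("tidy and glance expose the study in long and one-row form", {
  cfg <- sim_config(N = 100, H = 10, sigma = 0.25, R = 3, B = 30, seed = 4)
  sim <- run_unconditional(cfg)
  long <- tidy(sim)
  expect_setequal(unique(long$metric), c("bias", "rmse", "cv"))
  expect_equal(nrow(long), 3 * 3)
  g <- glance(sim)
  expect_equal(g$H, 10)
  expect_equal(g$true_var, sim$true_var)
  p <- autoplot(sim)
  expect_s3_class(p, "ggplot")
})
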