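#' Simulation scenario configuration
#'
#' Bundles and validates the settings of a design-based comparison study:
#' population size `N` split into `H` evenly sized strata on the score grid
#' `x_i = i/H`, unit values `y_k = mu*(x_i) + sigma e_k` with standard
#' normal noise, SRSWOR of `n_per_stratum` units per stratum, and `R`
#' replicated samples from the one fixed population.
#'
#' @param N Population size (default 3000); must be divisible by `H`.
#' @param H Number of strata (the study uses 50, 100 and 200).
#' @param sigma Noise standard deviation (0, 0.25 or 0.5 in the study).
#' @param mean_fn Mean-shape id, see [mean_function()].
#' @param h Kernel bandwidth; default `1.5/H`, the midpoint of the smallest
#'   non-empty window `(1/H, 2/H)`.
#' @param n_per_stratum SRSWOR size per stratum (1 or 2; default 2).
#' @param R Number of replicated samples (default 1000).
#' @param B Bootstrap resamples per replicate (default 1000).
#' @param nstar Bootstrap resample size per pseudo-stratum (default 2).
#' @param boot_mode Bootstrap estimator mode, see [estimate_bootstrap()].
#' @param estimators Which estimators to run.
#' @param group_size Samples per conditional group (default 20, giving 50
#'   groups at `R = 1000`).
#' @param n_pseudo Optional fixed pseudo-stratum count for the bootstrap.
#' @param unit_x `"stratified_uniform"` draws each unit's auxiliary score
#'   uniformly on its stratum's interval `((i-1)/H, i/H]` (so the sample
#'   mean of the auxiliary varies between samples and conditional grouping
#'   is meaningful); `"grid"` pins unit scores to the stratum score.
#' @param seed Root seed; all sampling, noise and bootstrap substreams are
#'   derived from it deterministically (replicate `r` gets the same
#'   substream regardless of `R`).
#' @return A validated list of class `fs_sim_config`.
#' @export
sim_config <- function(N = 3000, H = 100, sigma = 0.25, mean_fn = "linear",
                       h = 1.5 / H, n_per_stratum = 2, R = 1000, B = 1000,
                       nstar = 2, boot_mode = "resample",
                       estimators = c("collapsed", "kernel", "bootstrap"),
                       group_size = 20, n_pseudo = NULL,
                       unit_x = c("stratified_uniform", "grid"), seed = 1) {
  unit_x <- match.arg(unit_x)
  mean_fn <- match.arg(mean_fn, mean_function_ids())
  estimators <- match.arg(estimators,
                          c("collapsed", "kernel", "bootstrap"),
                          several.ok = TRUE)
  if (N %% H != 0) {
    abort("`N` must be divisible by `H` (evenly sized strata)",
          class = "finestrat_config_error")
  }
  if (h <= 0) abort("`h` must be positive", class = "finestrat_config_error")
  if (R < 1) abort("`R` must be >= 1", class = "finestrat_config_error")
  if (!n_per_stratum %in% c(1, 2)) {
    abort("`n_per_stratum` must be 1 or 2", class = "finestrat_config_error")
  }
  structure(list(N = N, H = H, sigma = sigma, mean_fn = mean_fn, h = h,
                 n_per_stratum = n_per_stratum, R = R, B = B, nstar = nstar,
                 boot_mode = boot_mode, estimators = estimators,
                 group_size = group_size, n_pseudo = n_pseudo,
                 unit_x = unit_x, seed = as.integer(seed)),
            class = "fs_sim_config")
}

#' @export
print.fs_sim_config <- function(x, ...) {
  cat("<fs_sim_config> N =", x$N, " H =", x$H, " sigma =", x$sigma,
      " mean_fn =", x$mean_fn, "\n  h =", format(x$h),
      " n_i =", x$n_per_stratum, " R =", x$R, " B =", x$B,
      " mode =", x$boot_mode, " seed =", x$seed, "\n")
  invisible(x)
}

#' Generate a synthetic stratified population
#'
#' Builds the fixed finite population of a scenario: `H` strata of
#' `N/H` units with stratum scores `x_i = i/H`, unit values
#' `y_k = mu*(x_i) + sigma e_k` (`mu*` the mean shape rescaled to `[0, 2]`,
#' `e_k` iid standard normal), and unit auxiliary scores per the `unit_x`
#' option. The noise is drawn once; the population then stays fixed while
#' samples are replicated from it.
#'
#' @param config An [sim_config()].
#' @return A `strat_pop` tibble.
#' @export
make_population <- function(config) {
  stopifnot(inherits(config, "fs_sim_config"))
  H <- config$H
  Ni <- config$N / H
  mu_star <- rescale_mean(mean_function(config$mean_fn))
  set.seed(derive_seed(config$seed, 0L, "population"))
  i <- rep(seq_len(H), each = Ni)
  x <- i / H
  y <- mu_star(x) + config$sigma * rnorm(config$N)
  xu <- if (config$unit_x == "stratified_uniform") {
    runif(config$N, min = (i - 1) / H, max = i / H)
  } else {
    x
  }
  stratified_population(tibble::tibble(
    stratum = sprintf("S%04d", i), x = x, xu = xu, y = y))
}

#' Unconditional comparison study
#'
#' Draws `R` independent stratified SRSWOR samples from one fixed synthetic
#' population and computes the selected variance estimators on each. The
#' summary compares each estimator's empirical design moments with the true
#' design variance `V = sum(V_i)` from [true_variance()]:
#' bias `= mean(V_hat) - V`, RMSE `= sqrt(mean((V_hat - V)^2))`, and
#' CV `= sd(V_hat)/mean(V_hat)`. Per-replicate estimator failures are
#' recorded, not fatal.
#'
#' @param config An [sim_config()].
#' @return An object of class `fs_sim`: list with the `config`, the true
#'   variance `true_var`, the per-replicate long tibble `replicates`
#'   (`replicate`, `xbar`, `estimator`, `value`) and the `summary` tibble.
#'   [tidy()] returns the summary in long metric format; [glance()] the
#'   scenario settings.
#' @export
run_unconditional <- function(config) {
  stopifnot(inherits(config, "fs_sim_config"))
  pop <- make_population(config)
  strata <- pop_strata(pop)
  V <- sum(true_variance(pop, config$n_per_stratum)$Vi)
  plan <- if ("collapsed" %in% config$estimators) make_pairing(strata)
  W <- if ("kernel" %in% config$estimators) kernel_weights(strata$x, config$h)
  reps <- purrr::map(seq_len(config$R), function(r) {
    s <- draw_srswor(pop, config$n_per_stratum,
                     seed = derive_seed(config$seed, r, "sampling"))
    xbar <- mean(s$xu)
    tt <- ht_totals(s)
    vals <- purrr::map_dbl(config$estimators, function(e) {
      tryCatch(switch(e,
        collapsed = v_collapsed(tt$that, plan)$value,
        kernel    = v_kernel(tt$that, W)$value,
        bootstrap = estimate_bootstrap(
          s, B = config$B, nstar = config$nstar, mode = config$boot_mode,
          n_pseudo = config$n_pseudo,
          seed = derive_seed(config$seed, r, "bootstrap"))$value),
        error = function(e) NA_real_)
    })
    tibble::tibble(replicate = r, xbar = xbar,
                   estimator = config$estimators, value = vals)
  })
  replicates <- dplyr::bind_rows(reps)
  summary <- dplyr::summarise(
    dplyr::group_by(replicates, .data$estimator),
    n_ok = sum(!is.na(.data$value)),
    bias = mean(.data$value, na.rm = TRUE) - V,
    rmse = sqrt(mean((.data$value - V)^2, na.rm = TRUE)),
    cv = sd(.data$value, na.rm = TRUE) / mean(.data$value, na.rm = TRUE),
    .groups = "drop")
  structure(list(config = config, true_var = V, replicates = replicates,
                 summary = summary),
            class = "fs_sim")
}

#' @export
print.fs_sim <- function(x, ...) {
  cat("<fs_sim> ", x$config$mean_fn, " mean, H = ", x$config$H,
      ", sigma = ", x$config$sigma, ", R = ", x$config$R,
      "; true var(t_hat) = ", format(x$true_var), "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @rdname run_unconditional
#' @param x An `fs_sim`.
#' @param ... Unused.
#' @export
tidy.fs_sim <- function(x, ...) {
  tidyr::pivot_longer(x$summary, c("bias", "rmse", "cv"),
                      names_to = "metric", values_to = "value") |>
    dplyr::mutate(H = x$config$H, h = x$config$h, sigma = x$config$sigma,
                  mean_fn = x$config$mean_fn, .before = 1)
}

#' @rdname run_unconditional
#' @export
glance.fs_sim <- function(x, ...) {
  c <- x$config
  tibble::tibble(N = c$N, H = c$H, sigma = c$sigma, mean_fn = c$mean_fn,
                 h = c$h, n_per_stratum = c$n_per_stratum, R = c$R, B = c$B,
                 boot_mode = c$boot_mode, seed = c$seed,
                 true_var = x$true_var)
}

#' Conditional comparison study
#'
#' Orders the `R` replicated samples by the sample mean of the unit
#' auxiliary scores, forms consecutive groups of `group_size` (50 groups of
#' 20 at the default `R = 1000`), and computes within each group the mean
#' auxiliary level, the conditional bias `mean(V_hat) - V` and the
#' conditional RMSE (CRMSE). Equal group sizes make the equally weighted
#' average of the conditional biases reproduce the unconditional bias
#' exactly.
#'
#' @param config An [sim_config()], or an `fs_sim` already produced by
#'   [run_unconditional()] (reusing its replicates).
#' @return An object of class `fs_sim_cond`: the underlying `fs_sim` plus a
#'   `groups` tibble (`group`, `xbar`, `estimator`, `cond_bias`, `crmse`).
#' @export
run_conditional <- function(config) {
  sim <- if (inherits(config, "fs_sim")) config else run_unconditional(config)
  cfg <- sim$config
  if (cfg$R %% cfg$group_size != 0) {
    abort("`R` must be divisible by the conditional group size",
          class = "finestrat_config_error")
  }
  V <- sim$true_var
  rep_order <- dplyr::distinct(sim$replicates, .data$replicate, .data$xbar)
  rep_order <- dplyr::arrange(rep_order, .data$xbar, .data$replicate)
  rep_order$group <- rep(seq_len(cfg$R / cfg$group_size),
                         each = cfg$group_size)
  joined <- dplyr::left_join(sim$replicates,
                             rep_order[, c("replicate", "group")],
                             by = "replicate")
  groups <- dplyr::summarise(
    dplyr::group_by(joined, .data$group, .data$estimator),
    xbar = mean(.data$xbar),
    cond_bias = mean(.data$value, na.rm = TRUE) - V,
    crmse = sqrt(mean((.data$value - V)^2, na.rm = TRUE)),
    .groups = "drop")
  structure(c(unclass(sim), list(groups = groups)),
            class = c("fs_sim_cond", "fs_sim"))
}

#' @rdname run_conditional
#' @param x An `fs_sim_cond`.
#' @param ... Unused.
#' @export
tidy.fs_sim_cond <- function(x, ...) x$groups
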