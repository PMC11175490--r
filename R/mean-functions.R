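#' Benchmark mean functions
#'
#' The seven benchmark mean shapes used by the synthetic populations, on
#' `x` in `[0, 1]`:
#' linear `1 + 2(x - 0.5)`; quadratic `1 + 2(x - 0.5)^2`; bump (linear plus
#' a narrow Gaussian bump at 0.5); jump (linear up to 0.65, then the
#' constant 0.65); exponential `exp(-8x)`; cycle1 `2 + sin(2 pi x)` (one
#' full cycle); cycle4 `2 + sin(8 pi x)` (four cycles). They span correct,
#' locally correct and badly misspecified cases for estimators that smooth
#' over neighbouring strata.
#'
#' @param id One of `"linear"`, `"quadratic"`, `"bump"`, `"jump"`,
#'   `"exponential"`, `"cycle1"`, `"cycle4"`.
#' @return The raw mean function (a vectorised function of `x`).
#' @seealso [rescale_mean()] for the version standardised to range
#'   `[0, 2]`.
#' @export
mean_function <- function(id = mean_function_ids()) {
  id <- match.arg(id)
  switch(id,
    linear      = function(x) 1 + 2 * (x - 0.5),
    quadratic   = function(x) 1 + 2 * (x - 0.5)^2,
    bump        = function(x) 1 + 2 * (x - 0.5) + exp(-200 * (x - 0.5)^2),
    jump        = function(x) ifelse(x <= 0.65, 1 + 2 * (x - 0.5), 0.65),
    exponential = function(x) exp(-8 * x),
    cycle1      = function(x) 2 + sin(2 * pi * x),
    cycle4      = function(x) 2 + sin(8 * pi * x)
  )
}

#' @rdname mean_function
#' @export
mean_function_ids <- function() {
  c("linear", "quadratic", "bump", "jump", "exponential", "cycle1", "cycle4")
}

#' Rescale a mean function to range \[0, 2\]
#'
#' Standardises a bounded mean function on `[0, 1]` to
#' `mu*(x) = 2 (mu(x) - min mu) / (max mu - min mu)`, so every benchmark
#' shape has minimum 0 and maximum 2 and the noise level `sigma` is
#' comparable across shapes. Extrema are located on a dense grid
#' (`grid_n` points).
#'
#' @param mu A vectorised function on `[0, 1]`.
#' @param grid_n Grid size for locating the extrema (default `1e5 + 1`,
#'   i.e. exact spacing `1e-5`, which places breakpoints such as the jump
#'   shape's 0.65 on the grid).
#' @return The rescaled function.
#' @export
rescale_mean <- function(mu, grid_n = 1e5 + 1) {
  grid <- seq(0, 1, length.out = grid_n)
  vals <- mu(grid)
  mn <- min(vals)
  mx <- max(vals)
  if (mx - mn < 1e-12) {
    abort("cannot rescale a constant mean function (max = min)",
          class = "finestrat_undefined_rescale")
  }
  function(x) 2 * (mu(x) - mn) / (mx - mn)
}
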