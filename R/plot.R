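#' Plot an unconditional comparison study
#'
#' Dot plot of empirical bias and RMSE per estimator, with the true design
#' variance as reference for the estimate distribution panel.
#'
#' @param object An `fs_sim` from [run_unconditional()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fs_sim <- function(object, ...) {
  long <- tidy(object)
  long <- long[long$metric %in% c("bias", "rmse"), ]
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$estimator, y = .data$value,
                               fill = .data$estimator)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = sprintf("Variance-estimator comparison (%s mean, H = %d, sigma = %g)",
                      object$config$mean_fn, object$config$H,
                      object$config$sigma)) +
    ggplot2::theme_minimal()
}

#' Plot a conditional comparison study
#'
#' Conditional bias and CRMSE per group against the group-average sample
#' mean of the auxiliary score, one line per estimator.
#'
#' @param object An `fs_sim_cond` from [run_conditional()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fs_sim_cond <- function(object, ...) {
  long <- tidyr::pivot_longer(object$groups, c("cond_bias", "crmse"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$xbar, y = .data$value,
                               colour = .data$estimator)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "group mean of sample x-bar", y = NULL,
                  colour = "estimator") +
    ggplot2::theme_minimal()
}
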