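# Diagnostic figures: psychometric curves and bootstrap clouds.

#' Plot choice proportions with a fitted psychometric curve
#'
#' @param table A `proportion_table`.
#' @param fit Optional `psychometric_fit` overlaid as a smooth curve with
#'   PSE marked.
#' @return A ggplot object.
#' @export
plot_psychometric <- function(table, fit = NULL) {
  df <- data.frame(delta_ms = table$delta_ms,
                   prop = table$n_chose / table$n_total)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_ms, y = .data$prop)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::labs(
      x = "Duration difference, communicative - noncommunicative (ms)",
      y = "P(communicative judged longer)") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    xs <- seq(min(df$delta_ms), max(df$delta_ms), length.out = 200)
    curve_df <- data.frame(delta_ms = xs,
                           prop = boltzmann(xs, fit$x0_ms, fit$omega_ms))
    p <- p +
      ggplot2::geom_line(data = curve_df, colour = "firebrick") +
      ggplot2::geom_vline(xintercept = fit$pse_ms, linetype = "dashed",
                          colour = "firebrick")
  }
  p
}

#' Plot one or more bivariate bootstrap clouds
#'
#' Each cloud is the set of 1000 (pre-mean, post-mean) pairs from
#' [bootstrap_bivariate_mean()]; the identity line marks "no change".
#'
#' @param clouds A `bootstrap_cloud` or named list of them (one per group).
#' @return A ggplot object.
#' @export
plot_bootstrap_cloud <- function(clouds) {
  if (inherits(clouds, "bootstrap_cloud")) clouds <- list(group = clouds)
  df <- dplyr::bind_rows(lapply(names(clouds), function(g) {
    m <- clouds[[g]]$resampled_means
    data.frame(group = g, pre = m$pre_mean, post = m$post_mean)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pre, y = .data$post,
                                   colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "Bootstrapped pre-treatment mean PSE (ms)",
                  y = "Bootstrapped post-treatment mean PSE (ms)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
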