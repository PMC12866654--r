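#' Bland-Altman plot with mean-dependent limits
#'
#' Conventional Bland-Altman plot of one method pair with the four-line
#' layout of the study figures: the mean difference (solid), the flat
#' limits of agreement (dotted), the regression of the difference on the
#' mean (solid), and, when the log branch was entered, the back-transformed
#' mean-dependent limits `slope * X` (dashed).
#'
#' @param paired a [paired_complete_cases()] sample.
#' @param result matching absolute-mode `bland_altman_result` from
#'   [adaptive_log_loa()]; computed if missing.
#' @return A `ggplot` object. Requires the suggested ggplot2 package.
#' @export
bland_altman_plot <- function(paired, result = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("bland_altman_plot requires the suggested package ggplot2")
  }
  if (is.null(result)) result <- adaptive_log_loa(paired, mode = "absolute")
  dd <- differences(paired, "absolute")
  df <- data.frame(mean = dd$means, diff = dd$d)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = result$mean_diff, colour = "red") +
    ggplot2::geom_hline(yintercept = c(result$loa_low, result$loa_high),
                        colour = "red", linetype = "dotted") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "blue", linewidth = 0.6) +
    ggplot2::labs(
      x = sprintf("Mean of %s and %s (mL)", paired$method1, paired$method2),
      y = sprintf("%s - %s (mL)", paired$method1, paired$method2)) +
    ggplot2::theme_minimal()
  if (!is.null(result$log_branch)) {
    lb <- result$log_branch
    p <- p +
      ggplot2::geom_abline(slope = lb$slope_low, intercept = 0,
                           colour = "darkgreen", linetype = "dashed") +
      ggplot2::geom_abline(slope = lb$slope_high, intercept = 0,
                           colour = "darkgreen", linetype = "dashed")
  }
  p
}
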