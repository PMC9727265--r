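# ggplot2 figures for the main result types.

#' Bland-Altman agreement plot
#'
#' Differences (protocol minus per-sample mean) against the per-sample
#' mean, with the bias and limits of agreement as horizontal lines and
#' flagged outliers highlighted.
#'
#' @param x A [bland_altman()] result.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(x) {
  stopifnot(inherits(x, "bland_altman_result"))
  ggplot2::ggplot(x$data, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_hline(yintercept = x$bias, linetype = 1) +
    ggplot2::geom_hline(yintercept = c(x$loa_lower, x$loa_upper),
                        linetype = 2) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$outlier), show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "red")) +
    ggplot2::labs(
      x = "Per-sample mean MESF",
      y = paste0("Difference (", x$protocol, " - mean)"),
      title = paste0("Bland-Altman: ", x$protocol),
      subtitle = paste0("bias ", signif(x$bias, 3), ", LoA [",
                        signif(x$loa_lower, 3), ", ",
                        signif(x$loa_upper, 3), "]")
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.bland_altman_result <- function(object, ...) {
  plot_bland_altman(object)
}

#' Calibration curve plot
#'
#' Bead peaks and the fitted log-log regression line.
#'
#' @param curve A [fit_calibration_curve()] result.
#' @param peaks The [find_bead_peaks()] result the curve was fitted to.
#' @param lot The matching [bead_lot()].
#' @return A ggplot object.
#' @export
plot_calibration <- function(curve, peaks, lot) {
  stopifnot(inherits(curve, "calibration_curve"))
  df <- tibble::tibble(log_mesf = log10(lot$mesf),
                       log_mfi = log10(peaks$mfi))
  ggplot2::ggplot(df, ggplot2::aes(x = log_mesf, y = log_mfi)) +
    ggplot2::geom_abline(intercept = curve$intercept, slope = curve$slope,
                         colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "log10 PE molecules per bead (MESF)",
      y = "log10 bead MFI",
      title = paste0("Calibration", if (!is.na(curve$protocol))
        paste0(": ", curve$protocol)),
      subtitle = paste0("slope ", signif(curve$slope, 4), ", intercept ",
                        signif(curve$intercept, 4), ", R² ",
                        signif(curve$r_squared, 4))
    ) +
    ggplot2::theme_minimal()
}

#' ROC curve plot
#'
#' @param x A [roc_analysis()] result.
#' @return A ggplot object with the Youden-optimal operating point marked.
#' @export
plot_roc <- function(x) {
  stopifnot(inherits(x, "roc_result"))
  df <- x$curve |>
    dplyr::arrange(1 - .data$specificity, .data$sensitivity)
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    ggplot2::geom_abline(intercept = 0, slope = 1, linetype = 3,
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::annotate("point", x = 1 - x$specificity, y = x$sensitivity,
                      colour = "red", size = 2) +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = paste0("ROC (AUC ", signif(x$auc, 3), ")"),
      subtitle = paste0("Youden cutoff ", signif(x$cutoff, 5), ", sens ",
                        signif(x$sensitivity, 3), ", spec ",
                        signif(x$specificity, 3))
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.roc_result <- function(object, ...) {
  plot_roc(object)
}
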