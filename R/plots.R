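#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a run's total ion current
#'
#' TIC versus time, with block boundaries overlaid when a layout is given.
#'
#' @param object A `run_table`.
#' @param layout Optional [session_layout()] whose block boundaries are
#'   drawn.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot run_table
#' @export
autoplot.run_table <- function(object, layout = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$time_min, y = .data$tic)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (min)", y = "total ion current (a.u.)") +
    ggplot2::theme_minimal()
  if (!is.null(layout)) {
    p <- p + ggplot2::geom_vline(xintercept = layout$blocks$t_start[-1],
                                 linetype = "dotted", colour = "grey40")
  }
  p
}

#' Plot per-scan ratios of a series
#'
#' Retained scans as points, excluded scans marked by exclusion reason;
#' block medians overlaid when the series is segmented.
#'
#' @param series A `ratio_series`.
#' @return A ggplot.
#' @export
plot_ratio_series <- function(series) {
  d <- tibble::as_tibble(series)
  d$status <- ifelse(d$retained, "retained", d$reason)
  ggplot2::ggplot(d[!is.na(d$ratio), ],
                  ggplot2::aes(x = .data$time_min, y = .data$ratio,
                               colour = .data$status)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.6) +
    ggplot2::labs(x = "time (min)", y = "isotopologue ratio",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a delta result
#'
#' Per-sample-block bracketed delta values (versus the working standard)
#' with the session mean and its standard deviation band.
#'
#' @param object A `delta_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot delta_result
#' @export
autoplot.delta_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$block,
                                  y = .data$delta_permil)) +
    ggplot2::geom_hline(yintercept = object$delta_vs_std,
                        colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$delta_vs_std +
                          c(-1, 1) * object$sd,
                        colour = "steelblue", linetype = "dashed") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "sample block",
                  y = expression(delta^13 * C ~ "vs working standard (‰)")) +
    ggplot2::theme_minimal()
}

#' Plot measured versus expected standards
#'
#' Residue plot for an evaluation report: per-standard residues with the
#' MAE annotated.
#'
#' @param report An `evaluation_report` from [mae()].
#' @return A ggplot.
#' @export
plot_residues <- function(report) {
  d <- tidy(report)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$label, y = .data$residue)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_col(width = 0.6, fill = "steelblue") +
    ggplot2::annotate("text", x = Inf, y = Inf, hjust = 1.1, vjust = 1.5,
                      label = sprintf("MAE = %.2f‰", report$mae)) +
    ggplot2::labs(x = NULL, y = "residue (measured - expected, ‰)") +
    ggplot2::theme_minimal()
}
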