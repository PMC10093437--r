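utils::globalVariables(c("proportion", "value", "metric", "center",
                         "correlation", "ci_low", "ci_high"))

# Figures: down-sampling scatter with trend lines (accuracy in black,
# consistency in red, following the usual presentation) and per-window
# rolling-correlation ribbons. All figure data live in the returned data
# frames/CSVs, so plots are regenerable without rerunning experiments.

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_contract("plotting requires the 'ggplot2' package")
}

#' Plot a down-sampling experiment
#'
#' Scatter of overall accuracy (black) and average error consistency (red)
#' against the sampled proportion, with locally weighted trend lines.
#' Points with undefined consistency appear as gaps, not zeros.
#'
#' @param points a `downsampling_points` data frame from
#'   [downsample_experiment()].
#' @param trend optional `trend_curve` from [fit_trend()]; fitted on the fly
#'   (span 0.75) when omitted and enough points are defined.
#' @return a ggplot object.
#' @export
plot_downsampling <- function(points, trend = NULL) {
  need_ggplot()
  if (is.null(trend) && sum(!is.na(points$aec)) >= 5 && nrow(points) >= 5)
    trend <- fit_trend(points)
  long <- rbind(
    data.frame(proportion = points$proportion, value = points$oa,
               metric = "OA"),
    data.frame(proportion = points$proportion, value = points$aec,
               metric = "AEC"))
  long <- long[!is.na(long$value), ]
  p <- ggplot2::ggplot(long, ggplot2::aes(x = proportion,
                                          y = value,
                                          colour = metric)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(OA = "black", AEC = "red")) +
    ggplot2::labs(x = "sample proportion", y = "metric value",
                  colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (!is.null(trend)) {
    tr <- rbind(
      data.frame(proportion = trend$x, value = trend$y_oa, metric = "OA"),
      data.frame(proportion = trend$x, value = trend$y_aec, metric = "AEC"))
    tr <- tr[!is.na(tr$value), ]
    p <- p + ggplot2::geom_line(data = tr, linewidth = 1)
  }
  p
}

#' Plot rolling-window correlations
#'
#' Correlation per window center with its bootstrap percentile ribbon.
#'
#' @param rc a `rolling_correlation` object.
#' @return a ggplot object.
#' @export
plot_rolling_correlation <- function(rc) {
  need_ggplot()
  df <- as.data.frame(rc)
  df <- df[!is.na(df$correlation), ]
  ggplot2::ggplot(df, ggplot2::aes(x = center, y = correlation)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = ci_low,
                                      ymax = ci_high),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "sample-size percentage (window center)",
                  y = sprintf("rolling %s correlation (window %d)",
                              attr(rc, "method"), attr(rc, "window_size"))) +
    ggplot2::ylim(-1, 1) +
    ggplot2::theme_minimal()
}
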