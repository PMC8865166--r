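# ggplot2 figures: mean change curves with standard-error ribbons, trend
# contrast summaries.

#' Mean change curve with standard-error band
#'
#' The canonical event-locked figure: grand-mean change (heart rate in bpm
#' or speed in km/h) against onset-relative time for the experimental and
#' control condition types, with +/-1 SE ribbons.
#'
#' @param epochs Long epoch tibble from [epoch_session()].
#' @param condition,window,channel Which slice to plot.
#' @return A ggplot object.
#' @export
plot_mean_change <- function(epochs, condition = "P", window = "postcue",
                             channel = "hr") {
  sub <- epochs[epochs$condition == condition & epochs$window == window &
                  epochs$channel == channel & !is.na(epochs$change), ]
  summ <- sub |>
    dplyr::group_by(.data$condition_type, .data$rel_time_s) |>
    dplyr::summarise(mean = mean(.data$change),
                     se = sd(.data$change) / sqrt(dplyr::n()),
                     .groups = "drop")
  ylab <- if (channel == "hr") "Heart rate change (bpm)" else "Speed change (km/h)"
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$rel_time_s, y = .data$mean,
                                     colour = .data$condition_type,
                                     fill = .data$condition_type)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted", colour = "grey40") +
    ggplot2::labs(x = sprintf("Time from %s onset (s)",
                              if (window == "postcue") "cue" else "event"),
                  y = ylab, colour = NULL, fill = NULL,
                  title = sprintf("%s condition, %s window", condition, window)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.trend_contrast <- function(object, ...) {
  sc <- as.data.frame(object$scores)
  sc <- tidyr::pivot_longer(sc, dplyr::everything(),
                            names_to = "order", values_to = "score")
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$order, y = .data$score)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_boxplot(width = 0.5, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.5, size = 1) +
    ggplot2::labs(x = NULL, y = "Per-participant contrast score",
                  title = "Polynomial trend contrast scores") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
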