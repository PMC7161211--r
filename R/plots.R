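# Condition colours follow the convention of the source figures:
# pre-exposure blue, immediately-post orange, 2-h-post green.
condition_colours <- c(A = "#1f77b4", B = "#ff7f0e", C = "#2ca02c")

#' Plot a chromatogram
#'
#' @param object A [chromatogram()].
#' @param peaks Optional `peak_table` to mark detected apexes.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.chromatogram <- function(object, peaks = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$rt, y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Retention time [min]", y = "Intensity",
                  title = sample_id(object)) +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks) > 0) {
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(rt = peaks$apex_rt_min, intensity = peaks$height),
      colour = "red", size = 0.8)
  }
  p
}

#' Plot group mean signals and difference curves
#'
#' Reproduces the standard layout for an exposure comparison: the three
#' per-condition mean signals (raw or moving-average filtered) as coloured
#' lines over retention time.
#'
#' @param object A `group_summary` from [compare_groups()].
#' @param signal `"filtered"` (default) or `"raw"`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.group_summary <- function(object, signal = c("filtered", "raw"), ...) {
  signal <- match.arg(signal)
  ggplot2::ggplot(object$means,
                  ggplot2::aes(x = .data$rt, y = .data[[signal]],
                               colour = .data$condition)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::scale_colour_manual(values = condition_colours, name = "Group") +
    ggplot2::labs(x = "Retention time [min]",
                  y = sprintf("Mean %s intensity", signal)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.group_summary
#' @param summary A `group_summary`.
#' @export
plot_diff_curves <- function(summary, signal = c("filtered", "raw")) {
  signal <- match.arg(signal)
  ggplot2::ggplot(summary$diff_curves,
                  ggplot2::aes(x = .data$rt, y = .data[[signal]],
                               colour = .data$comparison)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "Retention time [min]",
                  y = sprintf("Difference in mean %s intensity", signal),
                  colour = "Comparison") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
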