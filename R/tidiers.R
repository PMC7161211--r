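#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a group summary into its windowed statistics
#'
#' @param x A `group_summary` from [compare_groups()].
#' @param ... Unused.
#' @return The per-condition, per-window tibble of mean intensity, filtered
#'   mean and baseline estimate.
#' @exportS3Method generics::tidy
tidy.group_summary <- function(x, ...) {
  x$window_stats
}

#' One-row overview of a group comparison
#'
#' @param x A `group_summary`.
#' @param ... Unused.
#' @return A one-row tibble: sample counts per condition, grid size and
#'   span, filter window.
#' @exportS3Method generics::glance
glance.group_summary <- function(x, ...) {
  tibble::tibble(
    n_A = x$n_samples[["A"]], n_B = x$n_samples[["B"]],
    n_C = x$n_samples[["C"]],
    grid_points = length(x$grid),
    rt_min = min(x$grid), rt_max = max(x$grid),
    filter_window = x$filter$window)
}

#' Tidy a peak table to its persisted feature columns
#'
#' @param x A `peak_table` from [detect_peaks()].
#' @param ... Unused.
#' @return Tibble with the nine feature columns of the CSV schema.
#' @exportS3Method generics::tidy
tidy.peak_table <- function(x, ...) {
  tibble::as_tibble(x)[intersect(peak_csv_columns, names(x))]
}

#' One-row overview of a peak table
#'
#' @param x A `peak_table`.
#' @param ... Unused.
#' @return A one-row tibble: peak count, detection parameters, total area.
#' @exportS3Method generics::glance
glance.peak_table <- function(x, ...) {
  p <- peak_params(x) %||% list(prominence_min = NA_real_,
                                width_min = NA_real_, rel_height = NA_real_)
  tibble::tibble(n_peaks = nrow(x),
                 prominence_min = p$prominence_min,
                 width_min = p$width_min,
                 rel_height = p$rel_height,
                 total_area = sum(x$area))
}
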