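#' Common retention-time grid for a study
#'
#' Spans from the latest per-sample start time to the earliest per-sample end
#' time (so no sample is extrapolated), stepped at the median of the
#' per-sample median sampling intervals.
#'
#' @param study A `study_set`.
#' @return Numeric retention-time grid, minutes.
#' @export
common_grid <- function(study) {
  starts <- purrr::map_dbl(study$chromatogram, ~ .x$rt[1])
  ends <- purrr::map_dbl(study$chromatogram, ~ .x$rt[nrow(.x)])
  dts <- purrr::map_dbl(study$chromatogram, ~ stats::median(diff(.x$rt)))
  lo <- max(starts)
  hi <- min(ends)
  if (hi <= lo) abort_validation("samples share no retention-time overlap")
  seq(lo, hi, by = stats::median(dts))
}

#' Resample a chromatogram onto a retention-time grid
#'
#' Linear interpolation of the intensity onto `grid`. Grid points outside
#' the chromatogram's span are set to 0 and counted in a warning.
#'
#' @param chrom A [chromatogram()].
#' @param grid Numeric retention times, minutes.
#' @return Intensity series on `grid`.
#' @export
resample_to_grid <- function(chrom, grid) {
  validate_chromatogram(chrom)
  outside <- grid < chrom$rt[1] | grid > chrom$rt[nrow(chrom)]
  if (all(outside)) {
    abort_validation("grid does not overlap the chromatogram's retention span")
  }
  if (any(outside)) {
    warning(sprintf("%d grid point(s) outside sample '%s' set to 0",
                    sum(outside), sample_id(chrom)))
  }
  y <- stats::approx(chrom$rt, chrom$intensity, xout = grid, rule = 1)$y
  y[outside] <- 0
  y
}

qc_passing <- function(study, condition = NULL) {
  keep <- study$qc_pass
  if (!is.null(condition)) keep <- keep & study$condition == condition
  study[keep, ]
}

#' Per-condition mean signal on the common grid
#'
#' Pointwise arithmetic mean of the QC-passing samples of one condition,
#' each resampled onto the common grid, optionally moving-average filtered
#' per sample before averaging (by linearity this equals filtering the
#' mean).
#'
#' @param study A `study_set`.
#' @param condition `"A"`, `"B"` or `"C"`.
#' @param filter Optional [filter_spec()] (or odd window length) applied to
#'   each resampled sample before averaging.
#' @param grid Retention-time grid; defaults to [common_grid()] of the study.
#' @return Mean intensity series on the grid.
#' @export
group_mean <- function(study, condition, filter = NULL, grid = NULL) {
  if (is.null(grid)) grid <- common_grid(study)
  sub <- qc_passing(study, condition)
  if (nrow(sub) == 0) {
    abort_validation(sprintf("no QC-passing samples in condition %s", condition))
  }
  mats <- purrr::map(sub$chromatogram, resample_to_grid, grid = grid)
  if (!is.null(filter)) mats <- purrr::map(mats, moving_average, spec = filter)
  Reduce(`+`, mats) / length(mats)
}

#' Windowed intensity summary of a mean signal
#'
#' For each retention window, the mean intensity of the signal restricted to
#' the window and a robust baseline estimate, the 10th percentile of the
#' signal within the window (a low quantile is insensitive to peaks riding
#' on the baseline).
#'
#' @param y Intensity series on `grid`.
#' @param grid Retention times, minutes.
#' @param windows Window tibble as from [rt_windows()].
#' @return Tibble with columns `window`, `lo`, `hi`, `mean`, `baseline`, `n_points`.
#' @export
windowed_summary <- function(y, grid, windows = rt_windows(max(grid))) {
  purrr::map_dfr(seq_len(nrow(windows)), function(k) {
    w <- windows[k, ]
    sel <- in_window(grid, w)
    if (!any(sel)) {
      abort_validation(sprintf("window '%s' contains no grid points", w$window))
    }
    tibble::tibble(window = w$window, lo = w$lo, hi = w$hi,
                   mean = mean(y[sel]),
                   baseline = stats::quantile(y[sel], 0.10, names = FALSE),
                   n_points = sum(sel))
  })
}

#' Compare exposure groups
#'
#' Computes, for each condition, the mean raw and mean filtered signal on
#' the common grid from all QC-passing samples, pairwise difference curves
#' (B - A, C - A, B - C), and a per-condition windowed summary table over
#' the early/mid/late retention windows.
#'
#' @param study A `study_set` (run [qc_filter()] first to exclude failed
#'   measurements).
#' @param filter [filter_spec()] (or window length) for the filtered means.
#' @param windows Window tibble as from [rt_windows()]; defaults to the
#'   standard windows over the grid span.
#' @return An object of class `group_summary`: a list with `grid`, `means`
#'   (long tibble: `rt`, `condition`, `raw`, `filtered`), `diff_curves`
#'   (long tibble: `rt`, `comparison`, `raw`, `filtered`), `window_stats`
#'   (tibble: `condition`, `window`, `lo`, `hi`, `mean`, `baseline`,
#'   `mean_filtered`, `n_samples`) and `n_samples` (named count per
#'   condition). Use [generics::tidy()] and [autoplot.group_summary()] on it.
#' @export
compare_groups <- function(study, filter = filter_spec(), windows = NULL) {
  grid <- common_grid(study)
  if (is.null(windows)) windows <- rt_windows(max(grid))
  conds <- c("A", "B", "C")
  n_samples <- vapply(conds, function(cn) nrow(qc_passing(study, cn)), integer(1))
  raw <- lapply(conds, function(cn) group_mean(study, cn, grid = grid))
  filt <- lapply(conds, function(cn) {
    group_mean(study, cn, filter = filter, grid = grid)
  })
  names(raw) <- names(filt) <- conds
  means <- purrr::map_dfr(conds, function(cn) {
    tibble::tibble(rt = grid, condition = cn, raw = raw[[cn]],
                   filtered = filt[[cn]])
  })
  means$condition <- factor(means$condition, levels = conds)
  pairs <- list(c("B", "A"), c("C", "A"), c("B", "C"))
  diff_curves <- purrr::map_dfr(pairs, function(p) {
    tibble::tibble(rt = grid,
                   comparison = paste0(p[1], "-", p[2]),
                   raw = raw[[p[1]]] - raw[[p[2]]],
                   filtered = filt[[p[1]]] - filt[[p[2]]])
  })
  window_stats <- purrr::map_dfr(conds, function(cn) {
    ws <- windowed_summary(raw[[cn]], grid, windows)
    wf <- windowed_summary(filt[[cn]], grid, windows)
    ws$mean_filtered <- wf$mean
    ws$condition <- cn
    ws$n_samples <- n_samples[[cn]]
    ws[c("condition", "window", "lo", "hi", "mean", "baseline",
         "mean_filtered", "n_samples")]
  })
  structure(list(grid = grid, means = means, diff_curves = diff_curves,
                 window_stats = window_stats, n_samples = n_samples,
                 filter = if (is.numeric(filter)) filter_spec(filter) else filter,
                 windows = windows),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("Group summary: grid of %d points (%.3f-%.3f min); samples A=%d B=%d C=%d\n",
              length(x$grid), min(x$grid), max(x$grid),
              x$n_samples[["A"]], x$n_samples[["B"]], x$n_samples[["C"]]))
  print(x$window_stats, ...)
  invisible(x)
}
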