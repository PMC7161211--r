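#' Moving-average low-pass filter specification
#'
#' @param window Odd positive window length in samples. The default of 301
#'   samples spans about 1.5 min at the default 0.005-min sampling interval,
#'   which suppresses individual peaks and leaves the slow trend that the
#'   group comparison works on.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(window = 301) {
  if (length(window) != 1 || !is.finite(window) || window < 1 ||
      window %% 2 != 1) {
    abort_param("filter window must be an odd positive integer")
  }
  structure(list(window = as.integer(window), edge_rule = "shrink"),
            class = "filter_spec")
}

#' Moving-average low-pass filter
#'
#' Centered moving average with the shrink edge rule: near the signal edges
#' the window is truncated to the available samples, so the output has the
#' same length as the input and a window of 1 is the identity. The filter is
#' linear in its input.
#'
#' @param y Numeric intensity series.
#' @param spec A [filter_spec()], or an odd window length.
#' @return Filtered series, same length as `y`.
#' @export
#' @examples
#' moving_average(c(1, 2, 3, 4, 5), 3)  # 1.5 2 3 4 4.5
moving_average <- function(y, spec = filter_spec()) {
  if (is.numeric(spec)) spec <- filter_spec(spec)
  h <- (spec$window - 1L) %/% 2L
  n <- length(y)
  if (h == 0L || n == 0L) return(as.double(y))
  cs <- cumsum(c(0, as.double(y)))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Robust signal-to-noise ratio of a chromatogram
#'
#' The noise level is estimated from the first differences of the signal:
#' `noise_sd = 1.4826 * median(|diff(y)|) / sqrt(2)`, the median-absolute-
#' deviation estimate of the scan-to-scan noise standard deviation, which is
#' insensitive to peaks and baseline drift. The signal magnitude is the 95th
#' percentile minus the median of the intensities, so the ratio is invariant
#' to adding a constant and to rescaling. A noiseless signal returns `Inf`
#' (always passes QC).
#'
#' @param chrom A [chromatogram()], or a numeric intensity series.
#' @return The signal-to-noise ratio (dimensionless).
#' @export
estimate_snr <- function(chrom) {
  y <- if (is.data.frame(chrom)) chrom$intensity else as.double(chrom)
  noise_sd <- noise_sd_mad(y)
  if (noise_sd == 0) return(Inf)
  (stats::quantile(y, 0.95, names = FALSE) - stats::median(y)) / noise_sd
}

#' @rdname estimate_snr
#' @param y Numeric intensity series.
#' @return `noise_sd_mad()` returns the estimated noise standard deviation.
#' @export
noise_sd_mad <- function(y) {
  1.4826 * stats::median(abs(diff(y))) / sqrt(2)
}

#' Flag low signal-to-noise samples in a study
#'
#' Failed measurements are excluded from downstream analysis on the basis of
#' a low signal-to-noise ratio. Samples below the threshold are flagged
#' (`qc_pass = FALSE` with the measured value in `qc_reason`) but never
#' deleted; downstream stages skip flagged samples.
#'
#' @param study A `study_set`.
#' @param snr_threshold Minimum acceptable SNR; samples strictly below it
#'   fail. The default of 5 is a conventional detection floor.
#' @return The study with `qc_pass`, `qc_reason` updated and a numeric `snr`
#'   column added.
#' @export
qc_filter <- function(study, snr_threshold = 5) {
  snr <- purrr::map_dbl(study$chromatogram, estimate_snr)
  study$snr <- snr
  study$qc_pass <- snr >= snr_threshold
  study$qc_reason <- ifelse(study$qc_pass, NA_character_,
                            sprintf("low SNR (%.3g)", snr))
  new_study_set(study)
}
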