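#' Find local maxima of a 1-D signal
#'
#' An interior index `i` is a local maximum when `y[i-1] < y[i] > y[i+1]`.
#' A flat-topped plateau strictly above both neighbours yields its middle
#' index (the lower of the two middles when the plateau has even length).
#' Endpoints are never returned; signals shorter than 3 samples have no
#' interior maxima and return an empty result.
#'
#' @param y Numeric intensity series.
#' @return Integer vector of apex indices (1-based), increasing.
#' @export
#' @examples
#' find_local_maxima(c(0, 1, 0))        # 2
#' find_local_maxima(c(0, 2, 2, 2, 0))  # 3 (plateau middle)
find_local_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  out <- integer(n %/% 2)
  m <- 0L
  i <- 2L
  while (i < n) {
    if (y[i - 1L] < y[i]) {
      j <- i
      while (j < n && y[j + 1L] == y[i]) j <- j + 1L
      if (j < n && y[j + 1L] < y[i]) {
        m <- m + 1L
        out[m] <- (i + j) %/% 2L
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out[seq_len(m)]
}

#' Topographic prominence of a peak
#'
#' Standard topographic prominence on a 1-D signal: from the apex, extend
#' left until a sample strictly higher than the apex or the start of the
#' signal; the left minimum is the lowest sample in that stretch (ties
#' resolved to the index closest to the apex), and symmetrically on the
#' right. Prominence is the apex height above the higher of the two minima;
#' the two minima's indices are the peak's bases.
#'
#' @param y Numeric intensity series.
#' @param i Apex index (1-based); must be a local maximum (plateau members
#'   allowed).
#' @return A list with `prominence`, `left_base`, `right_base`.
#' @export
#' @examples
#' peak_prominence(c(0, 5, 0), 2)  # prominence 5, bases 1 and 3
peak_prominence <- function(y, i) {
  n <- length(y)
  if (i < 2 || i > n - 1) {
    rlang::abort("apex index must be interior", class = "breathgc_contract_error")
  }
  # verify i sits on (a plateau of) a local maximum
  l <- i
  while (l > 1 && y[l - 1L] == y[i]) l <- l - 1L
  r <- i
  while (r < n && y[r + 1L] == y[i]) r <- r + 1L
  if (l == 1 || r == n || y[l - 1L] > y[i] || y[r + 1L] > y[i]) {
    rlang::abort(sprintf("index %d is not a local maximum", i),
                 class = "breathgc_contract_error")
  }
  pb <- prominence_walk(y, i)
  list(prominence = pb[1], left_base = as.integer(pb[2]),
       right_base = as.integer(pb[3]))
}

# Core walk, no contract checks; returns c(prominence, left_base, right_base).
prominence_walk <- function(y, i) {
  n <- length(y)
  apex <- y[i]
  j <- i
  left_min <- apex
  left_base <- i
  while (j > 1L && y[j - 1L] <= apex) {
    j <- j - 1L
    if (y[j] < left_min) {
      left_min <- y[j]
      left_base <- j
    }
  }
  j <- i
  right_min <- apex
  right_base <- i
  while (j < n && y[j + 1L] <= apex) {
    j <- j + 1L
    if (y[j] < right_min) {
      right_min <- y[j]
      right_base <- j
    }
  }
  c(apex - max(left_min, right_min), left_base, right_base)
}

#' Peak width at a relative height
#'
#' The width is measured at `eval_height = y[apex] - rel_height * prominence`:
#' the horizontal distance, in samples, between the points where the signal
#' crosses that height on either side of the apex, found by linear
#' interpolation between adjacent samples and bounded by the peak's bases.
#' `rel_height = 0.5` (the default throughout the package) gives the width at
#' half prominence; `rel_height = 0` degenerates to zero width at the apex
#' and `rel_height = 1` measures at the base level.
#'
#' @param y Numeric intensity series.
#' @param i Apex index (1-based).
#' @param prominence,left_base,right_base Prominence data for the apex, as
#'   returned by [peak_prominence()].
#' @param rel_height Fraction of the prominence, in `[0, 1]`, at which the
#'   width is evaluated.
#' @return A list with `width_samples`, `left_ip`, `right_ip` (fractional
#'   1-based indices of the crossings) and `eval_height`.
#' @export
peak_width <- function(y, i, prominence, left_base, right_base,
                       rel_height = 0.5) {
  if (!is.finite(rel_height) || rel_height < 0 || rel_height > 1) {
    abort_param("rel_height must lie in [0, 1]")
  }
  eval_height <- y[i] - rel_height * prominence
  j <- i
  while (j > left_base && y[j] > eval_height) j <- j - 1L
  left_ip <- as.double(j)
  if (y[j] < eval_height) {
    left_ip <- j + (eval_height - y[j]) / (y[j + 1L] - y[j])
  }
  j <- i
  while (j < right_base && y[j] > eval_height) j <- j + 1L
  right_ip <- as.double(j)
  if (y[j] < eval_height) {
    right_ip <- j - (eval_height - y[j]) / (y[j - 1L] - y[j])
  }
  list(width_samples = right_ip - left_ip, left_ip = left_ip,
       right_ip = right_ip, eval_height = eval_height)
}

#' Chord-subtracted peak area
#'
#' Trapezoidal integral of the signal between the peak's bases, minus the
#' trapezoidal integral of the straight chord joining the two base points,
#' clipped below at zero. Subtracting the chord makes the area invariant to
#' adding a constant to the whole signal.
#'
#' @param y Numeric intensity series.
#' @param rt Retention-time series (minutes), same length as `y`.
#' @param left_base,right_base Base indices (1-based) bracketing the peak.
#' @return Area in intensity x minutes.
#' @export
peak_area <- function(y, rt, left_base, right_base) {
  idx <- left_base:right_base
  raw <- pracma::trapz(rt[idx], y[idx])
  chord <- (y[left_base] + y[right_base]) / 2 * (rt[right_base] - rt[left_base])
  max(0, raw - chord)
}

#' Detect peaks in a chromatogram and extract their features
#'
#' Finds all local maxima, keeps those whose topographic prominence is at
#' least `prominence_min` and whose width at `rel_height` of the prominence
#' is at least `width_min` samples, and computes the full per-peak feature
#' set: apex retention time, height (absolute intensity at the apex),
#' prominence, width in samples and in minutes, chord-subtracted area, and
#' the base positions. The defaults (`prominence_min = 3000`,
#' `width_min = 8`) are the working point for breath total-ion signals,
#' where they retain on the order of 100-150 peaks per sample.
#'
#' @param chrom A [chromatogram()].
#' @param prominence_min Minimum topographic prominence, intensity units.
#' @param width_min Minimum width in samples (grid steps) at `rel_height`.
#' @param rel_height Fraction of prominence at which width is measured.
#' @return A `peak_table` tibble sorted by `apex_rt_min`, one row per peak,
#'   with the detection parameters recorded as an attribute (see
#'   [peak_params()]).
#' @export
detect_peaks <- function(chrom, prominence_min = 3000, width_min = 8,
                         rel_height = 0.5) {
  validate_chromatogram(chrom)
  if (prominence_min <= 0 || width_min <= 0) {
    abort_param("prominence_min and width_min must be positive")
  }
  if (!is.finite(rel_height) || rel_height < 0 || rel_height > 1) {
    abort_param("rel_height must lie in [0, 1]")
  }
  y <- chrom$intensity
  rt <- chrom$rt
  apexes <- find_local_maxima(y)
  params <- list(prominence_min = prominence_min, width_min = width_min,
                 rel_height = rel_height)
  empty <- tibble::tibble(
    sample_id = character(0), apex_index = integer(0),
    apex_rt_min = double(0), height = double(0), prominence = double(0),
    left_base = integer(0), right_base = integer(0),
    left_ip = double(0), right_ip = double(0),
    width_samples = double(0), width_min = double(0), area = double(0),
    left_base_rt = double(0), right_base_rt = double(0))
  if (length(apexes) == 0) return(new_peak_table(empty, params))

  prom <- vapply(apexes, function(i) prominence_walk(y, i), double(3))
  keep <- prom[1, ] >= prominence_min
  apexes <- apexes[keep]
  prom <- prom[, keep, drop = FALSE]
  if (length(apexes) == 0) return(new_peak_table(empty, params))

  wd <- mapply(function(i, p, lb, rb) {
    unlist(peak_width(y, i, p, lb, rb, rel_height))
  }, apexes, prom[1, ], prom[2, ], prom[3, ])
  keep <- wd["width_samples", ] >= width_min
  apexes <- apexes[keep]
  prom <- prom[, keep, drop = FALSE]
  wd <- wd[, keep, drop = FALSE]
  if (length(apexes) == 0) return(new_peak_table(empty, params))

  rt_at <- function(frac_idx) {
    stats::approx(seq_along(rt), rt, xout = frac_idx, rule = 2)$y
  }
  lb <- as.integer(prom[2, ])
  rb <- as.integer(prom[3, ])
  tab <- tibble::tibble(
    sample_id = sample_id(chrom),
    apex_index = apexes,
    apex_rt_min = rt[apexes],
    height = y[apexes],
    prominence = prom[1, ],
    left_base = lb,
    right_base = rb,
    left_ip = wd["left_ip", ],
    right_ip = wd["right_ip", ],
    width_samples = wd["width_samples", ],
    width_min = rt_at(wd["right_ip", ]) - rt_at(wd["left_ip", ]),
    area = mapply(function(l, r) peak_area(y, rt, l, r), lb, rb),
    left_base_rt = rt[lb],
    right_base_rt = rt[rb])
  tab <- tab[order(tab$apex_rt_min), ]
  new_peak_table(tab, params)
}
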