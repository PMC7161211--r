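#' Construct a chromatogram
#'
#' A chromatogram is one breath sample's total-ion signal: a tibble with a
#' strictly increasing retention-time column `rt` (minutes) and an absolute
#' intensity column `intensity` (instrument units), optionally a
#' `relative_intensity` column in percent of the maximum. Sample identity and
#' any instrument header text travel along as attributes.
#'
#' @param rt Numeric vector of retention times in minutes, strictly increasing,
#'   length at least 2.
#' @param intensity Numeric vector of absolute intensities, same length as `rt`,
#'   all finite.
#' @param relative_intensity Optional numeric vector in `[0, 100]`; never used
#'   in computation (it is recomputable from `intensity`).
#' @param sample_id Opaque sample identifier string.
#' @param meta Named list of free-form metadata; header lines read from an
#'   instrument export are stored under `meta$header`.
#'
#' @return A tibble of class `chromatogram` with columns `rt`, `intensity` and
#'   optionally `relative_intensity`, carrying `sample_id` and `meta`
#'   attributes.
#' @export
#' @examples
#' chromatogram(rt = c(0.1, 0.2, 0.3), intensity = c(5, 7, 4), sample_id = "s01")
chromatogram <- function(rt, intensity, relative_intensity = NULL,
                         sample_id = "sample", meta = list()) {
  df <- tibble::tibble(rt = as.double(rt), intensity = as.double(intensity))
  if (!is.null(relative_intensity)) {
    df$relative_intensity <- as.double(relative_intensity)
  }
  x <- tibble::new_tibble(df, class = "chromatogram",
                          sample_id = as.character(sample_id), meta = meta)
  validate_chromatogram(x)
}

#' Sample identifier of a chromatogram
#' @param x A `chromatogram`.
#' @return The sample id string.
#' @export
sample_id <- function(x) attr(x, "sample_id") %||% "sample"

#' Validate a chromatogram's invariants
#'
#' Checks that retention times are strictly increasing, that `rt` and
#' `intensity` have equal length of at least 2, that intensities are finite,
#' and that `relative_intensity` (when present) lies in `[0, 100]`.
#'
#' @param x A `chromatogram`.
#' @return `x`, invisibly unchanged, or an error of class
#'   `breathgc_validation_error`.
#' @export
validate_chromatogram <- function(x) {
  rt <- x$rt
  y <- x$intensity
  if (length(rt) != length(y)) {
    abort_validation("rt and intensity must have equal length")
  }
  if (length(rt) < 2) {
    abort_validation("chromatogram must contain at least 2 scans",
                     class = "breathgc_empty_signal_error")
  }
  bad <- which(diff(rt) <= 0)
  if (length(bad) > 0) {
    abort_validation(sprintf(
      "retention time not strictly increasing at row %d (rt[%d] = %g, rt[%d] = %g)",
      bad[1] + 1L, bad[1], rt[bad[1]], bad[1] + 1L, rt[bad[1] + 1L]))
  }
  if (!all(is.finite(y))) {
    abort_validation(sprintf("non-finite intensity at row %d",
                             which(!is.finite(y))[1]))
  }
  rel <- x[["relative_intensity"]]
  if (!is.null(rel) && any(rel < 0 | rel > 100, na.rm = TRUE)) {
    abort_validation("relative_intensity must lie in [0, 100]")
  }
  x
}

#' Read a GC-MS instrument text export
#'
#' Instrument exports are plain-text files with one scan per row in columns
#' retention time, absolute intensity and (optionally) relative intensity.
#' Any leading lines whose first token is not parseable as a number are
#' treated as header text and captured into `meta$header`. Fields may be
#' separated by runs of spaces/tabs or by single commas; decimal points only.
#'
#' @param source Path to a text file, or a character vector of lines.
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension (or `"sample"` for in-memory input).
#' @param rt_seconds If `TRUE`, retention times are interpreted as seconds and
#'   converted to minutes. By default files whose first retention time exceeds
#'   120 are rejected as probably recorded in seconds.
#' @return A validated [chromatogram()].
#' @export
read_gcms_text <- function(source, sample_id = NULL, rt_seconds = FALSE) {
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
    if (is.null(sample_id)) {
      sample_id <- sub("\\.[^.]*$", "", basename(source))
    }
  } else {
    lines <- unlist(strsplit(as.character(source), "\n", fixed = TRUE))
    if (is.null(sample_id)) sample_id <- "sample"
  }
  lines <- lines[nzchar(trimws(lines))]
  first_token <- vapply(lines, function(l) {
    strsplit(trimws(l), "[,\t ]+")[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  is_num <- !is.na(suppressWarnings(as.numeric(first_token)))
  n_header <- if (any(is_num)) which(is_num)[1] - 1L else length(lines)
  header <- if (n_header > 0) lines[seq_len(n_header)] else character(0)
  data_lines <- if (n_header < length(lines)) {
    lines[(n_header + 1L):length(lines)]
  } else {
    character(0)
  }
  if (length(data_lines) < 2) {
    abort_validation("fewer than 2 numeric rows in input",
                     class = "breathgc_empty_signal_error")
  }
  fields <- strsplit(trimws(data_lines), "[,\t ]+")
  nf <- lengths(fields)
  if (any(nf < 2)) {
    i <- which(nf < 2)[1]
    abort_parse(sprintf("line %d: expected at least 2 numeric fields, found %d",
                        n_header + i, nf[i]))
  }
  parse_col <- function(k, name) {
    v <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), k)))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      abort_parse(sprintf("line %d: field %d (%s) is not numeric",
                          n_header + i, k, name))
    }
    v
  }
  rt <- parse_col(1, "retention time")
  y <- parse_col(2, "absolute intensity")
  rel <- if (all(nf >= 3)) parse_col(3, "relative intensity") else NULL
  if (rt_seconds) {
    rt <- rt / 60
  } else if (rt[length(rt)] > 120) {
    abort_validation(paste0(
      "last retention time exceeds 120 minutes; if the file is in seconds, ",
      "re-read with rt_seconds = TRUE"))
  }
  chromatogram(rt, y, relative_intensity = rel, sample_id = sample_id,
               meta = list(header = header))
}

#' Write a chromatogram as an instrument-style text export
#'
#' Header lines stored in `meta$header` are written verbatim, followed by the
#' numeric block at 12 significant digits, so `read_gcms_text()` of the output
#' reproduces the signal and metadata.
#'
#' @param chrom A [chromatogram()].
#' @param dest Output file path.
#' @param digits Significant digits for the numeric block.
#' @return `dest`, invisibly.
#' @export
write_gcms_text <- function(chrom, dest, digits = 12) {
  validate_chromatogram(chrom)
  header <- attr(chrom, "meta")$header
  fmt <- function(v) formatC(v, digits = digits, format = "g")
  cols <- list(fmt(chrom$rt), fmt(chrom$intensity))
  if (!is.null(chrom[["relative_intensity"]])) {
    cols <- c(cols, list(fmt(chrom[["relative_intensity"]])))
  }
  body <- do.call(paste, c(cols, sep = "\t"))
  writeLines(c(header, body), dest)
  invisible(dest)
}

abort_validation <- function(msg, class = character(0)) {
  rlang::abort(msg, class = c(class, "breathgc_validation_error"))
}

abort_parse <- function(msg) {
  rlang::abort(msg, class = "breathgc_parse_error")
}

abort_io <- function(msg) {
  rlang::abort(msg, class = "breathgc_io_error")
}

abort_param <- function(msg) {
  rlang::abort(msg, class = "breathgc_parameter_error")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
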