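# Columns that make up the on-disk peak-table schema, in order.
peak_csv_columns <- c("sample_id", "apex_rt_min", "height", "prominence",
                      "width_samples", "width_min", "area",
                      "left_base_rt", "right_base_rt")

new_peak_table <- function(df, params) {
  tibble::new_tibble(df, class = "peak_table", params = params)
}

#' Detection parameters recorded with a peak table
#' @param x A `peak_table`.
#' @return Named list with `prominence_min`, `width_min`, `rel_height`.
#' @export
peak_params <- function(x) attr(x, "params")

#' Write a peak-feature table to CSV
#'
#' Writes one row per detected peak with columns `sample_id`, `apex_rt_min`,
#' `height`, `prominence`, `width_samples`, `width_min`, `area`,
#' `left_base_rt`, `right_base_rt`. The detection parameters used are echoed
#' at the top of the file as comment lines prefixed `#`, so the file is
#' self-describing; `read_peak_table()` restores them.
#'
#' @param table A `peak_table` from [detect_peaks()] (extra working columns
#'   are dropped on write).
#' @param dest Output CSV path.
#' @return `dest`, invisibly.
#' @export
write_peak_table <- function(table, dest) {
  stopifnot(is.data.frame(table))
  missing_cols <- setdiff(peak_csv_columns, names(table))
  if (length(missing_cols) > 0) {
    abort_validation(sprintf("peak table lacks column(s): %s",
                             paste(missing_cols, collapse = ", ")))
  }
  params <- peak_params(table)
  con <- file(dest, "w")
  on.exit(close(con))
  if (!is.null(params)) {
    writeLines(sprintf("# %s = %s", names(params),
                       vapply(params, format, character(1), digits = 12)), con)
  }
  out <- table[peak_csv_columns]
  for (k in setdiff(peak_csv_columns, "sample_id")) {
    out[[k]] <- formatC(out[[k]], digits = 12, format = "g")
  }
  writeLines(paste(peak_csv_columns, collapse = ","), con)
  if (nrow(out) > 0) {
    writeLines(do.call(paste, c(as.list(out), sep = ",")), con)
  }
  invisible(dest)
}

#' Read a peak-feature table from CSV
#'
#' The inverse of [write_peak_table()]: validates the column schema exactly,
#' parses `#`-prefixed comment lines back into the recorded detection
#' parameters, and reports the row and column of any non-numeric cell.
#'
#' @param source CSV path.
#' @return A `peak_table` tibble.
#' @export
read_peak_table <- function(source) {
  if (!file.exists(source)) abort_io(sprintf("no such file: %s", source))
  lines <- readLines(source, warn = FALSE)
  comment <- lines[startsWith(lines, "#")]
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  params <- NULL
  if (length(comment) > 0) {
    kv <- strsplit(sub("^#\\s*", "", comment), "\\s*=\\s*")
    params <- stats::setNames(
      lapply(kv, function(p) as.numeric(p[2])),
      vapply(kv, `[`, character(1), 1))
  }
  if (length(lines) == 0) abort_parse("peak table file has no header row")
  cols <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (!identical(sort(cols), sort(peak_csv_columns))) {
    extra <- setdiff(cols, peak_csv_columns)
    miss <- setdiff(peak_csv_columns, cols)
    abort_validation(sprintf(
      "peak table schema mismatch (unknown: %s; missing: %s)",
      paste(extra, collapse = ", "), paste(miss, collapse = ", ")),
      class = "breathgc_schema_error")
  }
  body <- lines[-1]
  cells <- strsplit(body, ",", fixed = TRUE)
  df <- stats::setNames(as.list(rep(NA, length(cols))), cols)
  for (k in seq_along(cols)) {
    v <- vapply(cells, `[`, character(1), k)
    if (cols[k] == "sample_id") {
      df[[k]] <- v
    } else {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad) > 0) {
        abort_parse(sprintf("non-numeric cell at row %d, column '%s': '%s'",
                            bad[1], cols[k], v[bad[1]]))
      }
      df[[k]] <- num
    }
  }
  df <- tibble::as_tibble(df)[peak_csv_columns]
  if (length(body) == 0) df <- df[0, ]
  new_peak_table(df, params = params)
}

new_study_set <- function(df) {
  tibble::new_tibble(df, class = "study_set")
}

#' Read a study manifest and load its chromatograms
#'
#' A manifest is a CSV with columns `path`, `subject_id`, `condition` mapping
#' one chromatogram text file per row to its subject and sampling condition
#' (`A` before exposure, `B` immediately after, `C` two hours after). Every
#' referenced file is loaded and validated; QC status starts as passing.
#'
#' @param source Manifest CSV path. Relative chromatogram paths are resolved
#'   against the manifest's directory.
#' @return A `study_set` tibble with one row per sample: `sample_id`,
#'   `subject_id`, `condition`, `qc_pass`, `qc_reason`, and a `chromatogram`
#'   list-column.
#' @export
read_manifest <- function(source) {
  if (!file.exists(source)) abort_io(sprintf("no such file: %s", source))
  man <- readr::read_csv(source, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("path", "subject_id", "condition")
  if (!all(need %in% names(man))) {
    abort_validation(sprintf("manifest must have columns %s",
                             paste(need, collapse = ", ")),
                     class = "breathgc_schema_error")
  }
  bad_cond <- setdiff(unique(man$condition), c("A", "B", "C"))
  if (length(bad_cond) > 0) {
    abort_validation(sprintf("condition outside {A, B, C}: %s",
                             paste(bad_cond, collapse = ", ")))
  }
  dup <- duplicated(man[c("subject_id", "condition")])
  if (any(dup)) {
    i <- which(dup)[1]
    abort_validation(sprintf("duplicate (subject_id, condition): (%s, %s)",
                             man$subject_id[i], man$condition[i]))
  }
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", man$path), man$path,
                  file.path(dirname(source), man$path))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort_io(sprintf("chromatogram file not found: %s", missing[1]))
  }
  chroms <- purrr::map2(paths, paste0(man$subject_id, "_", man$condition),
                        function(p, id) read_gcms_text(p, sample_id = id))
  new_study_set(tibble::tibble(
    sample_id = paste0(man$subject_id, "_", man$condition),
    subject_id = man$subject_id,
    condition = factor(man$condition, levels = c("A", "B", "C")),
    qc_pass = TRUE,
    qc_reason = NA_character_,
    chromatogram = chroms
  ))
}

#' Write a study set's chromatograms and manifest to a directory
#'
#' One text export per sample plus a `manifest.csv` (columns `path`,
#' `subject_id`, `condition`) that [read_manifest()] accepts.
#'
#' @param study A `study_set`.
#' @param dir Output directory, created if needed.
#' @return The manifest path, invisibly.
#' @export
write_study_files <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- paste0(study$sample_id, ".txt")
  purrr::walk2(study$chromatogram, file.path(dir, files), write_gcms_text)
  man <- tibble::tibble(path = files, subject_id = study$subject_id,
                        condition = as.character(study$condition))
  dest <- file.path(dir, "manifest.csv")
  readr::write_csv(man, dest, progress = FALSE)
  invisible(dest)
}
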