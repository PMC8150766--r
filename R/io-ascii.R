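#' Read a Bern-Barcelona-style two-column ASCII segment
#'
#' Each row holds one comma-separated sample pair from the two channels of a
#' bipolar pair. The class label is taken from the file name via a
#' configurable pattern (the public naming uses `Data_F_...` for focal /
#' epileptogenic and `Data_N_...` for non-focal).
#'
#' @param path file path.
#' @param fs sampling rate, Hz (the public data are 512 Hz).
#' @param label optional explicit label overriding filename inference.
#' @param es_pattern,nes_pattern regexes applied to the file name to infer
#'   the label when `label` is `NULL`.
#' @param expected_points if non-`NULL`, a differing row count raises a
#'   format warning (the segment is still returned at its actual length).
#' @return A dual-channel [new_segment()].
#' @export
read_bern_barcelona <- function(path, fs = 512, label = NULL,
                                es_pattern = "(^|[_[:space:]])F([_[:space:]]|$)|^F",
                                nes_pattern = "(^|[_[:space:]])N([_[:space:]]|$)|^N",
                                expected_points = NULL) {
  dat <- read_ascii_matrix(path, n_cols = 2)
  if (!is.null(expected_points) && nrow(dat) != expected_points) {
    warn(sprintf("%s: expected %d rows, found %d; returning actual length",
                 basename(path), expected_points, nrow(dat)))
  }
  label <- label %||% infer_label(basename(path), es_pattern, nes_pattern)
  new_segment(t(dat), fs = fs, label = label)
}

#' Read a Bonn-style single-column ASCII segment
#'
#' Subset F files (epileptogenic-zone interictal recordings) are labelled ES;
#' subset N files (non-epileptic-area recordings) NES.
#'
#' @inheritParams read_bern_barcelona
#' @param fs sampling rate, Hz (the public data are 173.61 Hz).
#' @return A single-channel [new_segment()].
#' @export
read_bonn <- function(path, fs = 173.61, label = NULL,
                      es_pattern = "^F", nes_pattern = "^N",
                      expected_points = NULL) {
  dat <- read_ascii_matrix(path, n_cols = 1)
  if (!is.null(expected_points) && nrow(dat) != expected_points) {
    warn(sprintf("%s: expected %d rows, found %d; returning actual length",
                 basename(path), expected_points, nrow(dat)))
  }
  label <- label %||% infer_label(basename(path), es_pattern, nes_pattern)
  new_segment(dat[, 1], fs = fs, label = label)
}

read_ascii_matrix <- function(path, n_cols) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("%s: empty file", basename(path)))
  parts <- strsplit(lines, ",", fixed = TRUE)
  if (any(lengths(parts) != n_cols)) {
    abort(sprintf("%s: expected %d comma-separated column(s)", basename(path), n_cols))
  }
  vals <- suppressWarnings(as.numeric(unlist(parts)))
  if (anyNA(vals)) abort(sprintf("%s: non-numeric token", basename(path)))
  matrix(vals, ncol = n_cols, byrow = TRUE)
}

infer_label <- function(fname, es_pattern, nes_pattern) {
  stem <- sub("\\.[^.]*$", "", fname)
  if (grepl(es_pattern, stem)) return("ES")
  if (grepl(nes_pattern, stem)) return("NES")
  NA_character_
}

#' Write ASCII segment dialects
#'
#' `write_bern_barcelona()` emits two comma-separated columns (one row per
#' sample pair); `write_bonn()` emits one column. Values are written with
#' enough digits for round-trip identity at double precision.
#'
#' @param segment an [new_segment()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bern_barcelona <- function(segment, path) {
  stopifnot(inherits(segment, "ieeg_segment"), nrow(segment$samples) == 2)
  lines <- paste(format(segment$samples[1, ], digits = 17, trim = TRUE, scientific = FALSE),
                 format(segment$samples[2, ], digits = 17, trim = TRUE, scientific = FALSE),
                 sep = ",")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_bern_barcelona
#' @export
write_bonn <- function(segment, path) {
  stopifnot(inherits(segment, "ieeg_segment"), nrow(segment$samples) == 1)
  writeLines(format(segment$samples[1, ], digits = 17, trim = TRUE, scientific = FALSE), path)
  invisible(path)
}

#' Read a lead-label table
#'
#' Two-column CSV `lead_id,class` mapping each lead to
#' `epileptogenic`, `non-epileptogenic` or `excluded`.
#'
#' @param path CSV path.
#' @return A tibble with columns `lead_id`, `class`.
#' @export
read_lead_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("lead_id", "class") %in% names(df))) {
    abort("lead table needs columns lead_id, class")
  }
  bad <- setdiff(unique(df$class), c("epileptogenic", "non-epileptogenic", "excluded"))
  if (length(bad) > 0) {
    abort(paste("unknown lead class:", paste(bad, collapse = ", ")))
  }
  tibble::as_tibble(df[, c("lead_id", "class")])
}
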