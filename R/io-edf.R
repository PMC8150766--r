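#' Write a recording to EDF
#'
#' Minimal European Data Format writer: 16-bit samples, one-second data
#' records, per-channel physical scaling from the data range. If the
#' recording length is not a whole number of seconds the last record is
#' zero-padded (with a warning).
#'
#' @param rec an [new_recording()]; `fs` must be a whole number.
#' @param path output `.edf` path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "ieeg_recording"))
  fs <- rec$fs
  if (fs != round(fs)) abort("write_edf requires an integer sampling rate")
  ns <- nrow(rec$samples)
  n <- ncol(rec$samples)
  n_rec <- ceiling(n / fs)
  if (n_rec * fs != n) {
    warn("recording length padded with zeros to a whole number of 1-s records")
    pad <- matrix(0, ns, n_rec * fs - n)
    rec$samples <- cbind(rec$samples, pad)
  }

  # physical range rounded to what the 8-char header field can carry, so the
  # header and the digitization use the same scale
  fit8 <- function(x) {
    for (d in 7:1) {
      s <- formatC(signif(x, d), format = "g", digits = d)
      if (nchar(s) <= 8) return(as.numeric(s))
    }
    as.numeric(s)
  }
  pmin_ <- vapply(apply(rec$samples, 1, min), fit8, 0)
  pmax_ <- vapply(apply(rec$samples, 1, max), fit8, 0)
  flat <- pmax_ - pmin_ <= 0
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767

  pad_field <- function(x, width) {
    x <- substr(format(x, trim = TRUE), 1, width)
    formatC(x, width = width, flag = "-")
  }
  num_field <- function(x, width) {
    for (d in 7:1) {
      s <- formatC(signif(x, d), format = "g", digits = d)
      if (nchar(s) <= width) return(pad_field(s, width))
    }
    pad_field(s, width)
  }

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(paste(s, collapse = ""), con, eos = NULL)

  header_bytes <- 256L + 256L * ns
  wr(pad_field("0", 8))
  wr(pad_field(rec$patient_id %||% "X", 80))
  wr(pad_field("Startdate 01-JAN-2000", 80))
  wr(pad_field("01.01.00", 8))
  wr(pad_field("00.00.00", 8))
  wr(pad_field(as.character(header_bytes), 8))
  wr(pad_field("", 44))
  wr(pad_field(as.character(n_rec), 8))
  wr(pad_field("1", 8))
  wr(pad_field(as.character(ns), 4))

  wr(vapply(rec$lead_ids, pad_field, "", width = 16))
  wr(rep(pad_field("", 80), ns))
  wr(rep(pad_field("uV", 8), ns))
  wr(vapply(pmin_, num_field, "", width = 8))
  wr(vapply(pmax_, num_field, "", width = 8))
  wr(rep(pad_field(as.character(dmin), 8), ns))
  wr(rep(pad_field(as.character(dmax), 8), ns))
  wr(rep(pad_field("", 80), ns))
  wr(rep(pad_field(as.character(fs), 8), ns))
  wr(rep(pad_field("", 32), ns))

  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((rec$samples[ch, idx] - pmin_[ch]) * scale[ch] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording with a lead-label table
#'
#' Reads a 16-bit EDF file, attaches the per-lead classes from `lead_table`
#' (see [read_lead_table()]) and drops leads marked `excluded` (bad leads and
#' functional-area electrodes are removed before any downstream stage).
#' Table rows naming leads absent from the file are collected in a
#' reconciliation report attached as attribute `"reconciliation"`, not fatal.
#'
#' @param path `.edf` path.
#' @param lead_table path to a lead CSV, or a tibble from [read_lead_table()],
#'   or `NULL` to leave classes unassigned.
#' @return An [new_recording()]; `attr(, "reconciliation")` is a tibble of
#'   unmatched table rows.
#' @export
read_edf <- function(path, lead_table = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))

  rd(8)                       # version
  patient_id <- rd(80)
  rd(80); rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))

  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)               # transducer
  for (i in seq_len(ns)) rd(8)                # dimension
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)               # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)               # reserved

  if (length(unique(spr)) != 1) abort("read_edf supports a single common sampling rate")
  fs <- spr[1] / rec_dur
  samples <- matrix(0, ns, n_rec * spr[1])
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2, endian = "little", signed = TRUE)
      samples[ch, ((r - 1) * spr[ch] + 1):(r * spr[ch])] <-
        (dig - dmin[ch]) * scale[ch] + pmin_[ch]
    }
  }

  rec <- new_recording(samples, fs = fs, patient_id = patient_id, lead_ids = labels)
  recon <- tibble::tibble(lead_id = character(), class = character())
  if (!is.null(lead_table)) {
    tab <- if (is.character(lead_table)) read_lead_table(lead_table) else tibble::as_tibble(lead_table)
    known <- tab$lead_id %in% labels
    recon <- tab[!known, ]
    cls <- tab$class[match(labels, tab$lead_id)]
    rec$lead_class <- cls
    keep <- is.na(cls) | cls != "excluded"
    rec$samples <- rec$samples[keep, , drop = FALSE]
    rec$lead_ids <- rec$lead_ids[keep]
    rec$lead_class <- rec$lead_class[keep]
  }
  attr(rec, "reconciliation") <- recon
  rec
}
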