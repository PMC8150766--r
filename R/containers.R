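#' In-memory containers for iEEG data
#'
#' `new_segment()` wraps a fixed-length single- or dual-channel window of
#' samples with its sampling rate and label; `new_recording()` wraps a
#' continuous multi-lead session. These are deliberately lightweight S3
#' records: downstream feature extraction, balance planning and evaluation
#' all return tibbles.
#'
#' @param samples numeric vector (one channel) or channels-by-time matrix.
#' @param fs sampling rate in Hz (> 0).
#' @param label `"ES"`, `"NES"` or `NA` (unknown).
#' @param patient_id,lead_id optional identifying strings.
#' @param t_start start time of the window within its source recording, s.
#' @return An object of class `ieeg_segment`.
#' @export
new_segment <- function(samples, fs, label = NA_character_,
                        patient_id = NA_character_, lead_id = NA_character_,
                        t_start = 0) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  stopifnot(is.matrix(samples), nrow(samples) %in% c(1L, 2L), fs > 0)
  if (!is.na(label) && !label %in% c("ES", "NES")) {
    abort("label must be 'ES', 'NES' or NA")
  }
  structure(
    list(samples = samples, fs = fs, label = label,
         patient_id = patient_id, lead_id = lead_id, t_start = t_start),
    class = "ieeg_segment"
  )
}

#' @rdname new_segment
#' @param lead_ids character vector, one unique id per channel.
#' @param lead_class per-lead class: `"epileptogenic"`, `"non-epileptogenic"`
#'   or `"excluded"`.
#' @return `new_recording()`: an object of class `ieeg_recording`.
#' @export
new_recording <- function(samples, fs, patient_id = NA_character_,
                          lead_ids = NULL, lead_class = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  stopifnot(is.matrix(samples), fs > 0)
  n_ch <- nrow(samples)
  lead_ids <- lead_ids %||% sprintf("L%02d", seq_len(n_ch))
  lead_class <- lead_class %||% rep(NA_character_, n_ch)
  if (length(lead_ids) != n_ch || anyDuplicated(lead_ids) > 0) {
    abort("lead_ids must be unique, one per channel")
  }
  ok <- is.na(lead_class) |
    lead_class %in% c("epileptogenic", "non-epileptogenic", "excluded")
  if (length(lead_class) != n_ch || !all(ok)) {
    abort("lead_class must be epileptogenic / non-epileptogenic / excluded / NA per channel")
  }
  structure(
    list(samples = samples, fs = fs, patient_id = patient_id,
         lead_ids = lead_ids, lead_class = lead_class),
    class = "ieeg_recording"
  )
}

#' @export
print.ieeg_segment <- function(x, ...) {
  cat(sprintf("<ieeg_segment> %d ch x %d pts @ %g Hz (%.3g s), label=%s\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs, x$label))
  invisible(x)
}

#' @export
print.ieeg_recording <- function(x, ...) {
  tab <- table(factor(x$lead_class,
                      levels = c("epileptogenic", "non-epileptogenic", "excluded")))
  cat(sprintf("<ieeg_recording> %d leads x %d pts @ %g Hz (%.3g s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, ncol(x$samples) / x$fs))
  cat(sprintf("  leads: %d epileptogenic, %d non-epileptogenic, %d excluded\n",
              tab[1], tab[2], tab[3]))
  invisible(x)
}

#' Number of sample points in a segment
#' @param segment an `ieeg_segment`.
#' @return integer count of time points.
#' @export
n_points <- function(segment) ncol(segment$samples)

seg_duration <- function(segment) ncol(segment$samples) / segment$fs

rec_duration <- function(rec) ncol(rec$samples) / rec$fs
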