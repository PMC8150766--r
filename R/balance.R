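#' Sliding-window stride that equalizes lead-imbalanced classes
#'
#' With `M` majority (non-epileptogenic) leads, `N` minority (epileptogenic)
#' leads and segment length `S` seconds, the minority leads are re-segmented
#' with an overlapping stride `slidsize = S * N / M`, rounded to the nearest
#' positive multiple of 0.5 s (so every window start and end falls on a whole
#' or half second) and clamped to `[0.5, S]`.
#'
#' @param M majority lead count.
#' @param N minority lead count; requires `M > N >= 1`.
#' @param S segment length, s.
#' @return Stride in seconds, a multiple of 0.5.
#' @examples
#' compute_slidsize(69, 4, 10)  # 0.5
#' @export
compute_slidsize <- function(M, N, S) {
  if (N < 1) abort("N must be >= 1")
  if (M <= N) abort("M must exceed N; no resampling needed otherwise")
  if (S <= 0) abort("S must be > 0")
  raw <- S * N / M
  slid <- round(raw / 0.5) * 0.5
  min(max(slid, 0.5), S)
}

#' Segment counts for the non-overlapping and sliding enumerations
#'
#' `n_nonoverlap = floor(dur / S)` windows at stride `S`;
#' `m_sliding = fix((dur - S) / slidsize)` additional windows at the sliding
#' stride (fix truncates toward zero).
#'
#' @param dur continuous recording duration, s.
#' @param S segment length, s.
#' @param slidsize sliding stride, s.
#' @return Named list `n_nonoverlap`, `m_sliding`.
#' @export
count_segments <- function(dur, S, slidsize) {
  if (dur < S) return(list(n_nonoverlap = 0L, m_sliding = 0L))
  list(n_nonoverlap = as.integer(dur %/% S),
       m_sliding = as.integer(trunc((dur - S) / slidsize)))
}

#' Balance a lead-imbalanced session into labelled segments
#'
#' Majority-class (non-epileptogenic) leads are segmented non-overlapping at
#' stride `S`; minority-class (epileptogenic) leads are segmented with the
#' overlapping stride from [compute_slidsize()], which approximately
#' equalizes the pooled per-class segment counts.
#'
#' @param rec an [new_recording()] with `lead_class` assigned (`excluded`
#'   leads are ignored).
#' @param S segment length, s.
#' @return List of labelled segments; `attr(, "plan")` is a one-row tibble
#'   with `M`, `N`, `slidsize` and the per-class counts.
#' @export
balance_dataset <- function(rec, S = 10) {
  stopifnot(inherits(rec, "ieeg_recording"))
  keep <- !is.na(rec$lead_class) & rec$lead_class != "excluded"
  epi <- which(keep & rec$lead_class == "epileptogenic")
  non <- which(keep & rec$lead_class == "non-epileptogenic")
  if (length(epi) == 0) abort("no epileptogenic lead present")
  M <- length(non); N <- length(epi)
  dur <- rec_duration(rec)

  subset_rec <- function(idx) {
    new_recording(rec$samples[idx, , drop = FALSE], fs = rec$fs,
                  patient_id = rec$patient_id, lead_ids = rec$lead_ids[idx],
                  lead_class = rec$lead_class[idx])
  }

  segs_non <- if (M > 0) segment_recording(subset_rec(non), S, S) else list()
  if (M > N) {
    slid <- compute_slidsize(M, N, S)
    # the printed sliding count excludes the origin window: starts at k*slidsize
    segs_epi <- segment_recording(subset_rec(epi), S, slid, start_offset = TRUE)
  } else {
    slid <- S
    segs_epi <- segment_recording(subset_rec(epi), S, S)
  }
  if (dur < S) warn("recording shorter than one segment; nothing emitted")

  out <- c(segs_epi, segs_non)
  attr(out, "plan") <- tibble::tibble(
    M = M, N = N, S = S, slidsize = slid, dur = dur,
    n_es = length(segs_epi), n_nes = length(segs_non))
  out
}
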