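#' Confusion counts and classification metrics
#'
#' `confusion_counts()` tallies TP/TN/FP/FN from labels and predictions
#' (positive class = ES); `compute_metrics()` turns counts into accuracy,
#' sensitivity and specificity.
#'
#' @param truth,prediction vectors of `"ES"`/`"NES"` labels (or 1/0).
#' @return `confusion_counts()`: one-row tibble `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, prediction) {
  to01 <- function(v) if (is.character(v)) as.integer(v == "ES") else as.integer(v)
  y <- to01(truth); p <- to01(prediction)
  stopifnot(length(y) == length(p), length(y) > 0)
  tibble::tibble(tp = sum(y == 1 & p == 1), tn = sum(y == 0 & p == 0),
                 fp = sum(y == 0 & p == 1), fn = sum(y == 1 & p == 0))
}

#' @rdname confusion_counts
#' @param counts one-row tibble or list with `tp`, `tn`, `fp`, `fn`.
#' @return `compute_metrics()`: one-row tibble `acc`, `se`, `sp`
#'   (proportions); metrics with a zero denominator are `NA` with a warning,
#'   never silently 0.
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  if (total == 0) abort("empty confusion counts")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warn(sprintf("%s undefined (zero denominator)", what))
      return(NA_real_)
    }
    num / den
  }
  tibble::tibble(acc = (tp + tn) / total,
                 se = safe_div(tp, tp + fn, "sensitivity"),
                 sp = safe_div(tn, tn + fp, "specificity"))
}

#' Build a split plan
#'
#' Three schemes: `random_holdout` (stratified train/test),
#' `intra_subject` (stratified train/val/test within each patient), and
#' `cross_subject` (leave-one-subject-out: one fold per held-out patient,
#' train and test never share a patient).
#'
#' @param dataset tibble with at least `segment_id` and `label`
#'   (`patient_id` required for the subject-aware schemes).
#' @param scheme split scheme.
#' @param fractions split fractions summing to 1: length 2
#'   (train/test) for `random_holdout`, length 3 (train/val/test) for
#'   `intra_subject`.
#' @param seed RNG seed for the stratified assignment.
#' @return Tibble `segment_id`, `fold`, `role` (`train`/`val`/`test`); for
#'   `cross_subject` one block per fold.
#' @export
make_split <- function(dataset,
                       scheme = c("random_holdout", "intra_subject", "cross_subject"),
                       fractions = c(0.7, 0.3), seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(all(c("segment_id", "label") %in% names(dataset)))
  if (scheme != "cross_subject" && abs(sum(fractions) - 1) > 1e-9) {
    abort("fractions must sum to 1")
  }
  roles <- if (length(fractions) == 2) c("train", "test") else c("train", "val", "test")

  assign_stratified <- function(df) {
    out <- rep(NA_character_, nrow(df))
    for (lab in unique(df$label)) {
      idx <- which(df$label == lab)
      idx <- idx[sample.int(length(idx))]
      n <- length(idx)
      counts <- floor(fractions * n)
      counts[1] <- counts[1] + (n - sum(counts))
      out[idx] <- rep(roles, counts)
    }
    out
  }

  with_seed(seed, {
    if (scheme == "random_holdout") {
      tibble::tibble(segment_id = dataset$segment_id, fold = 1L,
                     role = assign_stratified(dataset))
    } else if (scheme == "intra_subject") {
      stopifnot("patient_id" %in% names(dataset))
      if (length(fractions) != 3) abort("intra_subject needs train/val/test fractions")
      dataset |>
        group_by(.data$patient_id) |>
        mutate(role = assign_stratified(dplyr::pick(dplyr::everything())),
               fold = 1L) |>
        ungroup() |>
        select("segment_id", "fold", "role")
    } else {
      stopifnot("patient_id" %in% names(dataset))
      pats <- unique(dataset$patient_id)
      if (length(pats) < 2) abort("cross_subject requires >= 2 patients")
      bind_rows(lapply(seq_along(pats), function(k) {
        tibble::tibble(segment_id = dataset$segment_id, fold = k,
                       role = ifelse(dataset$patient_id == pats[k], "test", "train"))
      }))
    }
  })
}

#' Aggregate per-fold metrics
#'
#' Arithmetic mean, standard error of the mean and range per metric across
#' folds (the clinical summaries report mean +/- SE with min-max range).
#'
#' @param per_fold tibble of per-fold metrics (e.g. columns `acc`, `se`,
#'   `sp`), one row per fold.
#' @return Tibble `metric`, `mean`, `sem`, `min`, `max`, `n_folds`. A
#'   single fold gives `sem` 0 with a warning.
#' @export
aggregate_folds <- function(per_fold) {
  if (nrow(per_fold) == 0) abort("no folds to aggregate")
  if (nrow(per_fold) == 1) warn("single fold: SE of the mean undefined, reporting 0")
  num <- per_fold[vapply(per_fold, is.numeric, TRUE)]
  bind_rows(imap(num, function(v, nm) {
    tibble::tibble(metric = nm, mean = mean(v),
                   sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else 0,
                   min = min(v), max = max(v), n_folds = length(v))
  }))
}

#' Format a results table
#'
#' One row per (method, feature set) with percent-formatted ACC/SE/SP, in
#' deterministic method order.
#'
#' @param results tibble with columns `method`, `feature_set`, `acc`, `se`,
#'   `sp` (proportions).
#' @return Tibble with the same rows, metrics formatted as `"97.60%"`.
#' @export
report_results <- function(results) {
  pct <- function(x) sprintf("%.2f%%", round(x * 100, 2))
  results |>
    arrange(.data$method) |>
    mutate(acc = pct(.data$acc), se = pct(.data$se), sp = pct(.data$sp))
}
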