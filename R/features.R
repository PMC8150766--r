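#' Feature-extraction configuration
#'
#' Parameters of the 70-dimensional multi-domain feature vector. Defaults
#' follow the printed choices (sample entropy m = 2, r = 0.2 sigma;
#' permutation order D = 3; Renyi alpha = 2; Kraskov k = 4; 5 IMFs); the
#' remaining knobs (fuzzy-entropy m/r, Higuchi k_max, SVD embedding, Welch
#' window, histogram bins) are unstated upstream and exposed here.
#'
#' @param sampen_m,sampen_r sample-entropy embedding and tolerance factor
#'   (times the sub-band SD).
#' @param perment_D permutation-entropy order.
#' @param renyi_alpha Renyi order.
#' @param kraskov_k nearest-neighbour index.
#' @param fuzzy_m,fuzzy_r fuzzy-entropy embedding and tolerance factor
#'   (times the IMF SD).
#' @param n_imfs IMFs extracted by EMD.
#' @param higuchi_kmax Higuchi maximum scale.
#' @param svd_embed_dim SVD-entropy embedding dimension (delay 1).
#' @param welch_window_seconds Welch segment length, s.
#' @param hist_bins histogram bin count for Renyi/Shannon probabilities;
#'   `NULL` means `ceiling(sqrt(n))`.
#' @return A `feature_config` list.
#' @export
feature_config <- function(sampen_m = 2, sampen_r = 0.2, perment_D = 3,
                           renyi_alpha = 2, kraskov_k = 4,
                           fuzzy_m = 2, fuzzy_r = 0.2, n_imfs = 5,
                           higuchi_kmax = 10, svd_embed_dim = 10,
                           welch_window_seconds = 1, hist_bins = NULL) {
  structure(as.list(environment()), class = "feature_config")
}

#' Feature manifest
#'
#' Fixed order and naming of the 70 features: 12 time-domain, 6
#' frequency-domain, 2 EMD fuzzy-entropy quartiles, then 10 entropy/fractal
#' measures for each of the five sub-bands A4, D4, D3, D2, D1.
#'
#' @return A 70-row tibble with columns `index`, `name`, `family`.
#' @export
feature_manifest <- function() {
  td <- c("mean", "variance", "cv", "skewness", "kurtosis", "iqr",
          "hjorth_activity", "hjorth_mobility", "hjorth_complexity",
          "zero_crossings", "hurst", "dfa")
  fd <- c("spr", "psd_mean", "asd_mean", "spectral_centroid",
          "spectral_kurtosis", "spectral_entropy")
  tf <- c("emd_fuzzy_q1", "emd_fuzzy_q3")
  ent <- c("kraskov", "renyi", "permutation", "sample", "shannon",
           "energy", "svd", "pfd", "kfd", "hfd")
  bands <- c("A4", "D4", "D3", "D2", "D1")
  nl <- as.vector(t(outer(ent, bands, paste, sep = "_")))
  tibble::tibble(
    index = 1:70,
    name = c(td, fd, tf, nl),
    family = rep(c("time", "frequency", "tf", "nonlinear"), c(12, 6, 2, 50)))
}

#' Time-domain features
#'
#' The 12 printed statistics: mean, population variance, coefficient of
#' variation, skewness, excess kurtosis, IQR (by the (N+1)p order-statistic
#' rule), Hjorth activity/mobility/complexity, zero-crossing count,
#' rescaled-range Hurst exponent and DFA scaling exponent.
#'
#' @param x numeric vector, length >= 3 (the derivative-based and scaling
#'   statistics need longer inputs to be meaningful and fall back to 0
#'   sentinels below their own minima).
#' @return Named numeric vector of length 12.
#' @export
time_domain_features <- function(x) {
  n <- length(x)
  stopifnot(n >= 3)
  mu <- mean(x)
  v <- sum((x - mu)^2) / n                      # population variance
  sdev <- sqrt(v)
  cv <- if (mu == 0) 0 else sdev / mu
  skw <- if (v == 0) 0 else {
    (sum((x - mu)^3) / n) / (sum((x - mu)^2) / (n - 1))^1.5
  }
  kur <- if (v == 0) 0 else (sum((x - mu)^4) / n) / v^2 - 3
  iqr <- quantile(x, 0.75, type = 6, names = FALSE) -
    quantile(x, 0.25, type = 6, names = FALSE)  # (N+1)p rule
  dx <- diff(x); ddx <- diff(dx)
  vd <- sum((dx - mean(dx))^2) / length(dx)
  vdd <- sum((ddx - mean(ddx))^2) / length(ddx)
  mob <- if (v == 0) 0 else sqrt(vd / v)
  com <- if (vd == 0 || mob == 0) 0 else sqrt(vdd / vd) / mob
  sgn <- sign(x)
  zc <- sum(abs(diff(sgn))) / 2
  c(mean = mu, variance = v, cv = cv, skewness = skw, kurtosis = kur,
    iqr = iqr, hjorth_activity = v, hjorth_mobility = mob,
    hjorth_complexity = com, zero_crossings = zc,
    hurst = hurst_rs(x), dfa = dfa_alpha(x))
}

#' Welch power spectral density
#'
#' Hann-windowed averaged periodogram with 50% overlap.
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param window_seconds segment length, s (clamped to the series length).
#' @return Tibble with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, window_seconds = 1) {
  n <- length(x)
  nw <- min(n, max(8, round(window_seconds * fs)))
  hop <- max(1, nw %/% 2)
  starts <- seq(1, n - nw + 1, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nw - 1) / (nw - 1))
  u <- sum(w^2)
  nf <- nw %/% 2 + 1
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nw - 1)] * w
    p <- Mod(fft(seg))^2 / (fs * u)
    acc <- acc + p[seq_len(nf)]
  }
  psd <- acc / length(starts)
  if (nw %% 2 == 0) psd[2:(nf - 1)] <- 2 * psd[2:(nf - 1)]
  else psd[2:nf] <- 2 * psd[2:nf]
  tibble::tibble(freq = (seq_len(nf) - 1) * fs / nw, psd = psd)
}

#' Frequency-domain features
#'
#' Six spectral summaries from the Welch PSD of the wide-band signal: the
#' sub-band power ratio SPR (60-140 Hz over 0-60 Hz band power), mean PSD,
#' mean amplitude spectral density, spectral centroid, spectral kurtosis
#' (fourth moment about the centroid over the squared variance), and
#' spectral entropy normalized by the log of the spectrum length.
#'
#' If the Nyquist rate leaves the 60-140 Hz numerator band empty, SPR is 0
#' with a warning.
#'
#' @param x numeric vector (wide-band, i.e. before the 80 Hz low cut).
#' @param fs sampling rate, Hz.
#' @param cfg a [feature_config()].
#' @return Named numeric vector of length 6.
#' @export
frequency_domain_features <- function(x, fs, cfg = feature_config()) {
  sp <- welch_psd(x, fs, cfg$welch_window_seconds)
  f <- sp$freq; p <- sp$psd
  num <- f > 60 & f <= 140
  den <- f >= 0 & f <= 60
  if (!any(num)) {
    warn("Nyquist below 60 Hz: SPR numerator band empty, returning 0")
    spr <- 0
  } else {
    spr <- sum(p[num]) / sum(p[den])
  }
  psd_mean <- mean(p)
  asd_mean <- mean(sqrt(p))
  tot <- sum(p)
  sc <- if (tot == 0) 0 else sum(f * p) / tot
  spread2 <- if (tot == 0) 0 else sum((f - sc)^2 * p) / tot
  sk <- if (spread2 == 0) 0 else (sum((f - sc)^4 * p) / tot) / spread2^2
  pn <- p / max(tot, .Machine$double.eps)
  pn <- pn[pn > 0]
  se <- -sum(pn * log(pn)) / log(length(p))
  c(spr = spr, psd_mean = psd_mean, asd_mean = asd_mean,
    spectral_centroid = sc, spectral_kurtosis = sk, spectral_entropy = se)
}

#' EMD fuzzy-entropy quartile features
#'
#' Decomposes the signal into up to `n_imfs` IMFs, computes the fuzzy
#' entropy of each, and returns the first and third sample quartiles of
#' those values.
#'
#' @param x numeric vector, length >= 64.
#' @param cfg a [feature_config()].
#' @return Named numeric vector `emd_fuzzy_q1`, `emd_fuzzy_q3`.
#' @export
emd_fuzzy_features <- function(x, cfg = feature_config()) {
  imfs <- emd(x, n_imfs = cfg$n_imfs)
  if (length(imfs) < 2) {
    warn("fewer than 2 IMFs extracted; returning sentinel quartiles 0")
    return(c(emd_fuzzy_q1 = 0, emd_fuzzy_q3 = 0))
  }
  fe <- vapply(imfs, function(im) {
    fuzzy_entropy(im, m = cfg$fuzzy_m, r = cfg$fuzzy_r * sd(im))
  }, 0)
  q <- quantile(fe, c(0.25, 0.75), type = 7, names = FALSE)
  c(emd_fuzzy_q1 = q[1], emd_fuzzy_q3 = q[2])
}

#' Sub-band entropy and fractal features
#'
#' Ten measures per sub-band (A4, D4, D3, D2, D1): Kraskov k-NN entropy,
#' Renyi entropy, permutation entropy, sample entropy, Shannon entropy,
#' energy, SVD entropy, Petrosian, Katz and Higuchi fractal dimensions.
#'
#' @param sb a `subband_set` from [decompose_subbands()].
#' @param cfg a [feature_config()].
#' @return Named numeric vector of length 50 in manifest order.
#' @export
subband_entropy_features <- function(sb, cfg = feature_config()) {
  bands <- c("A4", "D4", "D3", "D2", "D1")
  out <- numeric(0)
  for (fn in c("kraskov", "renyi", "permutation", "sample", "shannon",
               "energy", "svd", "pfd", "kfd", "hfd")) {
    for (b in bands) {
      x <- sb$coeffs[[b]]
      val <- switch(fn,
        kraskov = kraskov_entropy(x, k = cfg$kraskov_k),
        renyi = renyi_entropy(x, alpha = cfg$renyi_alpha,
                              p = hist_probs(x, cfg$hist_bins)),
        permutation = perm_entropy(x, D = cfg$perment_D),
        sample = sample_entropy(x, m = cfg$sampen_m, r = cfg$sampen_r * sd(x)),
        shannon = shannon_entropy(x, p = hist_probs(x, cfg$hist_bins)),
        energy = sum(x^2),
        svd = svd_entropy(x, embed_dim = cfg$svd_embed_dim),
        pfd = petrosian_fd(x),
        kfd = katz_fd(x),
        hfd = higuchi_fd(x, kmax = cfg$higuchi_kmax))
      out[paste(fn, b, sep = "_")] <- val
    }
  }
  out
}

#' Extract the 70-dimensional feature vector of one (sub-)segment
#'
#' Frequency-domain features are computed on the wide-band input at its
#' native rate (so the 60-140 Hz SPR numerator is observable); the
#' time-domain, EMD and sub-band blocks are computed on the band-passed
#' signal at the common analysis rate. Dual-channel segments are averaged
#' (time series for the scalar blocks, wavelet coefficients level-wise).
#'
#' @param segment an [new_segment()].
#' @param cfg a [preprocess_config()].
#' @param fcfg a [feature_config()].
#' @param filtered `TRUE` if the segment is already band-passed.
#' @return Named numeric vector of length 70 in [feature_manifest()] order.
#' @export
extract_feature_vector <- function(segment, cfg = preprocess_config(),
                                   fcfg = feature_config(), filtered = FALSE) {
  wide <- colMeans(segment$samples)
  fd <- frequency_domain_features(wide, segment$fs, fcfg)
  seg_f <- if (filtered) segment else {
    bandpass(segment, cfg$bandpass[1], min(cfg$bandpass[2], segment$fs / 2 * 0.98),
             cfg$filter_order)
  }
  seg_a <- resample_segment(seg_f, cfg$analysis_fs)
  x <- colMeans(seg_a$samples)
  td <- time_domain_features(x)
  tf <- emd_fuzzy_features(x, fcfg)
  sb <- decompose_subbands(seg_a, cfg)
  nl <- subband_entropy_features(sb, fcfg)
  out <- c(td, fd, tf, nl)
  stopifnot(length(out) == 70)
  out
}

#' Extract the timestep feature sequence of a segment
#'
#' Splits the segment into `n` non-overlapping timesteps and extracts the
#' 70-feature vector per timestep: `n x 70` scalars (280 for the default 4).
#'
#' @inheritParams extract_feature_vector
#' @param n number of timesteps (defaults to `cfg$n_timesteps`).
#' @return Matrix `n x 70` with manifest column names.
#' @export
extract_feature_sequence <- function(segment, cfg = preprocess_config(),
                                     fcfg = feature_config(),
                                     n = cfg$n_timesteps, filtered = FALSE) {
  steps <- split_timesteps(segment, n)
  do.call(rbind, lapply(steps, extract_feature_vector, cfg = cfg, fcfg = fcfg,
                        filtered = filtered))
}

#' Feature table for a list of segments
#'
#' Tidy interface over [extract_feature_sequence()]: one row per
#' (segment, timestep) with the 70 manifest-named feature columns.
#'
#' @param segments list of [new_segment()]s.
#' @inheritParams extract_feature_sequence
#' @return Tibble with `segment_id`, `label`, `patient_id`, `lead_id`,
#'   `timestep` and 70 feature columns.
#' @export
extract_feature_table <- function(segments, cfg = preprocess_config(),
                                  fcfg = feature_config(),
                                  n = cfg$n_timesteps, filtered = FALSE) {
  rows <- imap(segments, function(seg, i) {
    m <- extract_feature_sequence(seg, cfg, fcfg, n = n, filtered = filtered)
    tibble::as_tibble(m) |>
      mutate(segment_id = i, label = seg$label, patient_id = seg$patient_id,
             lead_id = seg$lead_id, timestep = dplyr::row_number() - 1L,
             .before = 1)
  })
  bind_rows(rows)
}
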