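#' Empirical mode decomposition
#'
#' Classic sifting: upper and lower envelopes are cubic splines through the
#' local maxima and minima (series endpoints are included as support points
#' to tame edge divergence), the mean envelope is subtracted until the
#' Cauchy-style stopping criterion `sum((h_prev - h)^2) / sum(h_prev^2)`
#' falls below `sd_stop`, and the IMF is peeled off. Extraction stops when
#' `n_imfs` components are found or the residual has fewer than 4 extrema.
#'
#' @param x numeric vector (length >= 64 for meaningful IMFs).
#' @param n_imfs maximum number of intrinsic mode functions.
#' @param sd_stop sifting stop threshold.
#' @param max_sift maximum sifting iterations per IMF.
#' @return List of IMF numeric vectors (possibly fewer than `n_imfs`);
#'   `attr(, "residual")` holds the final residual.
#' @export
emd <- function(x, n_imfs = 5, sd_stop = 0.2, max_sift = 50) {
  n <- length(x)
  imfs <- list()
  resid <- x
  t <- seq_len(n)
  for (k in seq_len(n_imfs)) {
    ext <- local_extrema(resid)
    if (length(ext$max) + length(ext$min) < 4) break
    h <- resid
    for (it in seq_len(max_sift)) {
      ext <- local_extrema(h)
      if (length(ext$max) < 2 || length(ext$min) < 2) break
      up <- spline(c(1, ext$max, n), c(h[1], h[ext$max], h[n]), xout = t)$y
      lo <- spline(c(1, ext$min, n), c(h[1], h[ext$min], h[n]), xout = t)$y
      m <- (up + lo) / 2
      h_new <- h - m
      crit <- sum((h - h_new)^2) / max(sum(h^2), .Machine$double.eps)
      h <- h_new
      if (crit < sd_stop) break
    }
    imfs[[k]] <- h
    resid <- resid - h
  }
  attr(imfs, "residual") <- resid
  imfs
}

# strict interior local maxima / minima indices
local_extrema <- function(x) {
  d <- diff(x)
  s <- sign(d)
  # collapse flat runs so plateaus count once
  idx <- which(s != 0)
  if (length(idx) < 2) return(list(max = integer(0), min = integer(0)))
  changes <- which(diff(s[idx]) != 0)
  pos <- idx[changes] + 1L
  kind <- s[idx][changes]
  list(max = pos[kind > 0], min = pos[kind < 0])
}
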