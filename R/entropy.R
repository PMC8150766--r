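#' Entropy and fractal-dimension primitives
#'
#' Scalar complexity measures used for the per-sub-band feature block. Each
#' follows the printed closed form; degenerate inputs (constant signals,
#' empty match sets) return 0 rather than NaN so downstream models never see
#' non-finite values.
#'
#' @name entropy-primitives
#' @param x numeric vector.
NULL

# delay-embedding matrix: rows are m-length windows at unit delay
embed_delay <- function(x, m, delay = 1) {
  n <- length(x) - (m - 1) * delay
  if (n < 1) abort("series too short for embedding")
  idx <- outer(seq_len(n), (0:(m - 1)) * delay, `+`)
  matrix(x[idx], nrow = n)
}

# Chebyshev distance matrix between rows of an embedding
cheb_dist <- function(emb) {
  n <- nrow(emb)
  d <- matrix(0, n, n)
  for (j in seq_len(ncol(emb))) {
    d <- pmax(d, abs(outer(emb[, j], emb[, j], `-`)))
  }
  d
}

#' @rdname entropy-primitives
#' @param m embedding dimension.
#' @param r tolerance in signal units (callers usually pass `0.2 * sd(x)`).
#' @return `sample_entropy()`: -ln(A/B) where A and B count template matches
#'   at dimensions m+1 and m (self-matches excluded).
#' @export
sample_entropy <- function(x, m = 2, r = 0.2 * sd(x)) {
  n <- length(x)
  if (n < m + 2 || !is.finite(r) || r <= 0) return(0)
  # common number of templates for both dimensions (standard SampEn)
  nt <- n - m
  emb_m <- embed_delay(x, m)[seq_len(nt), , drop = FALSE]
  emb_m1 <- embed_delay(x, m + 1)
  dB <- cheb_dist(emb_m); dA <- cheb_dist(emb_m1)
  B <- (sum(dB <= r) - nt) / 2
  A <- (sum(dA <= r) - nt) / 2
  if (A <= 0 || B <= 0) return(0)
  -log(A / B)
}

#' @rdname entropy-primitives
#' @return `fuzzy_entropy()`: ln(phi_m) - ln(phi_{m+1}) with Gaussian
#'   membership exp(-(d/r)^2) on baseline-removed templates.
#' @export
fuzzy_entropy <- function(x, m = 2, r = 0.2 * sd(x)) {
  n <- length(x)
  if (n < m + 2 || !is.finite(r) || r <= 0) return(0)
  phi <- function(dim) {
    emb <- embed_delay(x, dim)
    emb <- emb - rowMeans(emb)          # local baseline removal
    emb <- emb[seq_len(n - m), , drop = FALSE]
    d <- cheb_dist(emb)
    mu <- exp(-(d / r)^2)
    nt <- nrow(emb)
    (sum(mu) - nt) / (nt * (nt - 1))
  }
  pm <- phi(m); pm1 <- phi(m + 1)
  if (pm <= 0 || pm1 <= 0) return(0)
  log(pm) - log(pm1)
}

#' @rdname entropy-primitives
#' @param D ordinal pattern order.
#' @return `perm_entropy()`: permutation entropy normalized by log2(D!),
#'   in `[0, 1]`; 0 for a strictly monotone series.
#' @export
perm_entropy <- function(x, D = 3) {
  n <- length(x) - D + 1
  if (n < 1) return(0)
  emb <- embed_delay(x, D)
  pat <- apply(emb, 1, function(w) paste(order(w), collapse = ""))
  p <- table(pat) / n
  -sum(p * log2(p)) / log2(factorial(D))
}

# amplitude-histogram probabilities for the discrete entropies
hist_probs <- function(x, n_bins = NULL) {
  n_bins <- n_bins %||% max(2L, ceiling(sqrt(length(x))))
  rng <- range(x)
  if (diff(rng) == 0) return(1)
  counts <- tabulate(
    pmin(pmax(floor((x - rng[1]) / diff(rng) * n_bins) + 1, 1L), n_bins),
    nbins = n_bins)
  p <- counts / sum(counts)
  p[p > 0]
}

#' @rdname entropy-primitives
#' @param p optional probability vector; computed from an amplitude
#'   histogram of `x` when missing.
#' @param alpha Renyi order.
#' @return `renyi_entropy()`: (1/(1-alpha)) * log sum p^alpha (natural log).
#' @export
renyi_entropy <- function(x, alpha = 2, p = NULL) {
  p <- p %||% hist_probs(x)
  log(sum(p^alpha)) / (1 - alpha)
}

#' @rdname entropy-primitives
#' @return `shannon_entropy()`: -sum p log p (natural log).
#' @export
shannon_entropy <- function(x, p = NULL) {
  p <- p %||% hist_probs(x)
  -sum(p * log(p))
}

#' @rdname entropy-primitives
#' @param k neighbour index for the nearest-neighbour estimator.
#' @return `kraskov_entropy()`: Kozachenko-Leonenko k-NN differential
#'   entropy, `digamma(N) - digamma(k) + mean(log(2 * dist_k))` in 1-D.
#' @export
kraskov_entropy <- function(x, k = 4) {
  n <- length(x)
  if (n <= k) return(0)
  xs <- sort(x)
  # kth nearest neighbour distance via the sorted order
  dk <- vapply(seq_len(n), function(i) {
    lo <- max(1, i - k); hi <- min(n, i + k)
    sort(abs(xs[lo:hi] - xs[i]))[k + 1]
  }, 0)
  dk <- pmax(dk, .Machine$double.eps)
  digamma(n) - digamma(k) + mean(log(2 * dk))
}

#' @rdname entropy-primitives
#' @param embed_dim embedding dimension for the trajectory matrix.
#' @return `svd_entropy()`: entropy of the normalized squared singular-value
#'   spectrum, normalized by log(embed_dim).
#' @export
svd_entropy <- function(x, embed_dim = 10, delay = 1) {
  embed_dim <- min(embed_dim, max(2L, length(x) - 1L))
  emb <- embed_delay(x, embed_dim, delay)
  s <- svd(emb, nu = 0, nv = 0)$d
  e <- s^2
  if (sum(e) == 0) return(0)
  p <- e / sum(e)
  p <- p[p > 0]
  -sum(p * log(p)) / log(embed_dim)
}

#' @rdname entropy-primitives
#' @return `petrosian_fd()`: log(n) / (log(n) + log(n / (n + 0.4 * Ndelta)))
#'   with Ndelta the number of sign changes in the first difference.
#' @export
petrosian_fd <- function(x) {
  n <- length(x)
  dx <- diff(x)
  ndelta <- sum(diff(sign(dx)) != 0)
  log(n) / (log(n) + log(n / (n + 0.4 * ndelta)))
}

#' @rdname entropy-primitives
#' @return `katz_fd()`: log(n) / (log(d/L) + log(n)) with L the curve length
#'   and d the maximum distance from the first point.
#' @export
katz_fd <- function(x) {
  n <- length(x) - 1
  L <- sum(sqrt(1 + diff(x)^2))
  d <- max(sqrt((seq_along(x) - 1)^2 + (x - x[1])^2))
  if (L == 0 || d == 0) return(0)
  log(n) / (log(d / L) + log(n))
}

#' @rdname entropy-primitives
#' @param kmax maximum curve-length scale.
#' @return `higuchi_fd()`: least-squares slope of ln L(k) against ln(1/k).
#' @export
higuchi_fd <- function(x, kmax = 10) {
  n <- length(x)
  kmax <- min(kmax, n %/% 2)
  if (kmax < 2) return(0)
  Lk <- vapply(seq_len(kmax), function(k) {
    Lm <- vapply(seq_len(k), function(m) {
      idx <- seq(m, n, by = k)
      if (length(idx) < 2) return(NA_real_)
      norm_f <- (n - 1) / (k * (length(idx) - 1))
      sum(abs(diff(x[idx]))) * norm_f / k
    }, 0)
    mean(Lm, na.rm = TRUE)
  }, 0)
  ok <- Lk > 0
  if (sum(ok) < 2) return(0)
  stats::coef(stats::lm(log(Lk[ok]) ~ log(1 / seq_len(kmax)[ok])))[[2]]
}

#' @rdname entropy-primitives
#' @return `hurst_rs()`: rescaled-range exponent
#'   log_N(range(cumsum(x - mean)) / sd).
#' @export
hurst_rs <- function(x) {
  n <- length(x)
  s <- sd(x)
  if (!is.finite(s) || s == 0 || n < 4) return(0)
  L <- cumsum(x - mean(x))
  rs <- (max(L) - min(L)) / s
  if (rs <= 0) return(0)
  log(rs) / log(n)
}

#' @rdname entropy-primitives
#' @return `dfa_alpha()`: detrended-fluctuation scaling exponent from
#'   least-squares fit of log F(n) over dyadic window sizes 4..N/4.
#' @export
dfa_alpha <- function(x) {
  n <- length(x)
  if (n < 16) return(0)
  y <- cumsum(x - mean(x))
  sizes <- unique(pmin(4 * 2^(0:20), n %/% 4))
  sizes <- sizes[sizes >= 4]
  Fn <- vapply(sizes, function(w) {
    nw <- n %/% w
    res <- vapply(seq_len(nw), function(b) {
      seg <- y[((b - 1) * w + 1):(b * w)]
      t <- seq_len(w)
      fit <- stats::lm.fit(cbind(1, t), seg)
      mean(fit$residuals^2)
    }, 0)
    sqrt(mean(res))
  }, 0)
  ok <- Fn > 0
  if (sum(ok) < 2) return(0)
  stats::coef(stats::lm(log(Fn[ok]) ~ log(sizes[ok])))[[2]]
}
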