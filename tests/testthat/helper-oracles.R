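# Independent brute-force oracles for the entropy / fractal features.
# Deliberately naive loop implementations, kept separate from the package's
# vectorized code paths.

oracle_sampen <- function(x, m, r) {
  n <- length(x)
  count <- function(dim) {
    nt <- n - m                      # common template count for both dims
    tot <- 0L
    for (i in 1:(nt - 1)) {
      for (j in (i + 1):nt) {
        d <- 0
        for (k in 0:(dim - 1)) d <- max(d, abs(x[i + k] - x[j + k]))
        if (d <= r) tot <- tot + 1L
      }
    }
    tot
  }
  A <- count(m + 1); B <- count(m)
  -log(A / B)
}

oracle_fuzzyen <- function(x, m, r) {
  n <- length(x)
  phi <- function(dim) {
    nt <- n - m
    templ <- lapply(1:nt, function(i) {
      w <- x[i:(i + dim - 1)]
      w - mean(w)
    })
    s <- 0
    for (i in 1:nt) for (j in 1:nt) {
      if (i != j) {
        d <- max(abs(templ[[i]] - templ[[j]]))
        s <- s + exp(-(d / r)^2)
      }
    }
    s / (nt * (nt - 1))
  }
  log(phi(m)) - log(phi(m + 1))
}

oracle_permen <- function(x, D) {
  n <- length(x) - D + 1
  pats <- character(n)
  for (i in 1:n) pats[i] <- paste(order(x[i:(i + D - 1)]), collapse = "-")
  p <- as.numeric(table(pats)) / n
  -sum(p * log2(p)) / log2(factorial(D))
}

oracle_kraskov <- function(x, k) {
  n <- length(x)
  dk <- numeric(n)
  for (i in 1:n) {
    d <- sort(abs(x - x[i]))
    dk[i] <- max(d[k + 1], .Machine$double.eps)   # d[1] is the self distance
  }
  digamma(n) - digamma(k) + mean(log(2 * dk))
}

oracle_hist_probs <- function(x, nb) {
  br <- seq(min(x), max(x), length.out = nb + 1)
  cnt <- hist(x, breaks = br, plot = FALSE, right = FALSE,
              include.lowest = TRUE)$counts
  # right-open bins except the final bin, matching floor-based binning
  p <- cnt / sum(cnt)
  p[p > 0]
}

oracle_svd_entropy <- function(x, dim) {
  n <- length(x) - dim + 1
  M <- matrix(0, n, dim)
  for (i in 1:n) M[i, ] <- x[i:(i + dim - 1)]
  ev <- eigen(crossprod(M), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  p <- ev / sum(ev)
  p <- p[p > 1e-15]
  -sum(p * log(p)) / log(dim)
}

oracle_higuchi <- function(x, kmax) {
  n <- length(x)
  Lk <- numeric(kmax)
  for (k in 1:kmax) {
    Lm <- c()
    for (m in 1:k) {
      idx <- seq(m, n, by = k)
      if (length(idx) >= 2) {
        s <- 0
        for (q in 2:length(idx)) s <- s + abs(x[idx[q]] - x[idx[q - 1]])
        Lm <- c(Lm, s * (n - 1) / (k * (length(idx) - 1)) / k)
      }
    }
    Lk[k] <- mean(Lm)
  }
  fit <- lm(log(Lk) ~ log(1 / (1:kmax)))
  unname(coef(fit)[2])
}

oracle_quantile_sorted_np1 <- function(v, p) {
  # the (N+1)p order-statistic index rule with linear interpolation
  s <- sort(v)
  h <- (length(s) + 1) * p
  h <- min(max(h, 1), length(s))
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

oracle_quantile_sorted <- function(v, p) {
  # linear interpolation between order statistics at index 1 + p*(n-1)
  s <- sort(v)
  h <- 1 + p * (length(s) - 1)
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}
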