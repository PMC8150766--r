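# Minimal neural-network toolkit: dense layers, dropout, Adam, and the
# binary cross-entropy loss. Parameters live in nested named lists of
# matrices; gradients mirror that structure. Everything is plain matrix
# code so the training loop is deterministic given the R RNG seed.

nn_uniform_init <- function(nrow, ncol, fan_in = nrow) {
  b <- 1 / sqrt(fan_in)
  matrix(runif(nrow * ncol, -b, b), nrow, ncol)
}

dense_init <- function(n_in, n_out) {
  list(W = nn_uniform_init(n_in, n_out), b = matrix(runif(n_out, -1 / sqrt(n_in), 1 / sqrt(n_in)), 1))
}

dense_forward <- function(p, x) {
  out <- x %*% p$W
  out <- out + rep(as.numeric(p$b), each = nrow(out))
  list(out = out, x = x)
}

dense_backward <- function(p, cache, dout) {
  list(dx = dout %*% t(p$W),
       grads = list(W = t(cache$x) %*% dout, b = matrix(colSums(dout), 1)))
}

relu_forward <- function(x) list(out = pmax(x, 0), mask = x > 0)
relu_backward <- function(cache, dout) dout * cache$mask

sigmoid <- function(x) 1 / (1 + exp(-x))

# inverted dropout; identity in eval mode
dropout_forward <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(out = x, mask = NULL))
  mask <- (matrix(runif(length(x)), nrow(x)) >= rate) / (1 - rate)
  list(out = x * mask, mask = mask)
}
dropout_backward <- function(cache, dout) {
  if (is.null(cache$mask)) dout else dout * cache$mask
}

#' Binary cross-entropy loss
#'
#' `-[y log p + (1 - y) log(1 - p)]`, averaged over a batch; predictions are
#' clipped to `[1e-7, 1 - 1e-7]`.
#'
#' @param y true labels in `{0, 1}` (1 = ES).
#' @param y_hat predicted probabilities.
#' @return Mean loss in nats.
#' @export
bce_loss <- function(y, y_hat) {
  eps <- 1e-7
  p <- pmin(pmax(y_hat, eps), 1 - eps)
  mean(-(y * log(p) + (1 - y) * log(1 - p)))
}

bce_grad <- function(y, y_hat) {
  eps <- 1e-7
  p <- pmin(pmax(y_hat, eps), 1 - eps)
  (p - y) / (p * (1 - p)) / length(y)
}

# ---- parameter-tree utilities ---------------------------------------------

tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- mapply(tree_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    out
  } else {
    f(a, b)
  }
}

tree_zeros <- function(a) {
  if (is.list(a)) lapply(a, tree_zeros) else a * 0
}

adam_init <- function(params) {
  list(m = tree_zeros(params), v = tree_zeros(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- tree_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(state$m, state$v, function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- tree_map2(params, upd, `-`)
  list(params = params, state = state)
}

# minibatch index generator: shuffled, last short batch kept
make_batches <- function(n, batch_size) {
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}

# classification accuracy at threshold 0.5 (ties -> ES)
prob_accuracy <- function(y, p) mean(as.integer(p >= 0.5) == y)
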