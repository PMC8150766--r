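test_that("block output lengths match the conv/pool closed form", {
  cfg <- cnn_config(seed = 1)
  shape_oracle <- function(L) {
    for (cl in cfg$conv_layers) {
      L <- (L + 2 * cl[5] - cl[3]) %/% cl[4] + 1   # conv
      L <- L %/% cfg$pool_size                     # pool
    }
    L
  }
  params <- ieegfuse:::cnn_init(cfg)
  state <- ieegfuse:::cnn_state_init(cfg)
  for (L in c(128, 200, 333, 640, 1280)) {
    x <- matrix(rnorm(2 * L), 2, L)
    fwd <- ieegfuse:::cnn_forward(params, x, cfg, state, training = FALSE)
    blocks <- fwd$caches$blocks
    expect_equal(dim(blocks[[length(blocks)]]$mp$out)[2], shape_oracle(L))
    expect_equal(ncol(fwd$embedding), 128)
  }
})

test_that("channel progression follows the configured blocks", {
  set.seed(70)
  cfg <- cnn_config(epochs = 1, seed = 2)
  x <- matrix(rnorm(8 * 256), 8, 256)
  y <- rep(c(0, 1), 4)
  fit <- suppressWarnings(train_cnn(x, y, x, y, cfg))
  a1 <- activation_maps(fit, x[1, ], layer = 1)
  a2 <- activation_maps(fit, x[1, ], layer = 2)
  a4 <- activation_maps(fit, x[1, ], layer = 4)
  expect_equal(length(unique(a1$channel)), 16)
  expect_equal(length(unique(a2$channel)), 32)
  expect_equal(length(unique(a4$channel)), 32)
  expect_error(activation_maps(fit, x[1, ], layer = 9), "invalid")
})

test_that("conv and batch-norm gradients match finite differences", {
  set.seed(71)
  p <- ieegfuse:::conv1d_init(2, 3, 3)
  x <- array(rnorm(4 * 20 * 2), dim = c(4, 20, 2))
  fw <- ieegfuse:::conv1d_forward(p, x, stride = 1, pad = 1)
  dout <- array(rnorm(length(fw$out)), dim = dim(fw$out))
  bk <- ieegfuse:::conv1d_backward(p, fw$cache, dout)
  eps <- 1e-6
  loss_w <- function(w) {
    q <- p; q$W[2, 1, 3] <- w
    sum(ieegfuse:::conv1d_forward(q, x, 1, 1)$out * dout)
  }
  num <- (loss_w(p$W[2, 1, 3] + eps) - loss_w(p$W[2, 1, 3] - eps)) / (2 * eps)
  expect_equal(bk$grads$W[2, 1, 3], num, tolerance = 1e-6)

  loss_x <- function(v) {
    q <- x; q[2, 7, 1] <- v
    sum(ieegfuse:::conv1d_forward(p, q, 1, 1)$out * dout)
  }
  numx <- (loss_x(x[2, 7, 1] + eps) - loss_x(x[2, 7, 1] - eps)) / (2 * eps)
  expect_equal(bk$dx[2, 7, 1], numx, tolerance = 1e-6)

  bp <- ieegfuse:::bn_init(3)
  bp$gamma[1, ] <- runif(3, 0.5, 1.5)
  st <- list(mean = numeric(3), var = rep(1, 3))
  fb <- ieegfuse:::bn_forward(bp, fw$out, st, training = TRUE)
  bb <- ieegfuse:::bn_backward(bp, fb$cache, dout)
  loss_b <- function(v) {
    q <- fw$out; q[3, 5, 2] <- v
    sum(ieegfuse:::bn_forward(bp, q, st, TRUE)$out * dout)
  }
  numb <- (loss_b(fw$out[3, 5, 2] + eps) - loss_b(fw$out[3, 5, 2] - eps)) / (2 * eps)
  expect_equal(bb$dx[3, 5, 2], numb, tolerance = 1e-5)
})

test_that("eval-mode activations are invariant to input scaling after batch norm", {
  set.seed(72)
  cfg <- cnn_config(epochs = 2, seed = 3)
  x <- matrix(rnorm(16 * 200), 16, 200)
  y <- rep(c(0, 1), 8)
  fit <- train_cnn(x, y, x, y, cfg)
  # bypass the input scaler to probe raw batch-norm behaviour
  f1 <- ieegfuse:::cnn_forward(fit$params, x, cfg, fit$bn_state, training = FALSE)
  # batch-norm in eval mode uses frozen statistics: scaling the input scales
  # pre-norm activations but only shifts normalized values linearly; the
  # first conv is linear, so block-1 pre-activation scales exactly
  cv1 <- ieegfuse:::conv1d_forward(fit$params$blocks[[1]]$conv,
                                   array(x, dim = c(16, 200, 1)), 1, 1)
  cv2 <- ieegfuse:::conv1d_forward(fit$params$blocks[[1]]$conv,
                                   array(2 * x, dim = c(16, 200, 1)), 1, 1)
  bias <- as.numeric(fit$params$blocks[[1]]$conv$b)
  centered1 <- sweep(matrix(cv1$out, ncol = 16), 2, bias)
  centered2 <- sweep(matrix(cv2$out, ncol = 16), 2, bias)
  expect_equal(centered2, 2 * centered1, tolerance = 1e-9)
  expect_true(all(is.finite(f1$p)))
})

test_that("the CNN can overfit a tiny batch deterministically", {
  set.seed(73)
  n <- 20; L <- 128
  x <- matrix(rnorm(n * L), n, L)
  y <- rep(c(0, 1), n / 2)
  x[y == 1, 40:44] <- x[y == 1, 40:44] + 4
  cfg <- cnn_config(epochs = 25, batch_size = 20, seed = 4)
  fit <- train_cnn(x, y, x, y, cfg)
  expect_lt(min(fit$history$train_loss), 0.1)
  fit2 <- train_cnn(x, y, x, y, cfg)
  expect_identical(fit$history, fit2$history)
  expect_error(train_cnn(x, rep(1, n), x, y, cfg), "both classes")
})
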