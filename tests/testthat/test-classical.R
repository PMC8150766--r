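test_that("attention weights are a probability distribution matching softmax", {
  set.seed(60)
  dim_e <- 8
  params <- ieegfuse:::attention_init(dim_e)
  e <- lapply(1:4, function(t) matrix(rnorm(3 * dim_e), 3, dim_e))
  out <- attention(e, params)
  expect_equal(rowSums(out$h), rep(1, 3), tolerance = 1e-12)
  expect_true(all(out$h >= 0))

  # hand-rolled softmax of tanh(Ww e + bw)' uw
  scores <- sapply(1:4, function(t) {
    u <- tanh(sweep(e[[t]] %*% params$Ww, 2, params$bw, `+`))
    as.numeric(u %*% params$uw)
  })
  ref <- t(apply(scores, 1, function(s) exp(s) / sum(exp(s))))
  expect_equal(out$h, ref, tolerance = 1e-10)
  v_ref <- Reduce(`+`, lapply(1:4, function(t) ref[, t] * e[[t]]))
  expect_equal(out$v, v_ref, tolerance = 1e-10)
})

test_that("attention degenerates correctly for identical or single timesteps", {
  set.seed(61)
  params <- ieegfuse:::attention_init(6)
  e1 <- matrix(rnorm(2 * 6), 2, 6)
  same <- attention(list(e1, e1, e1), params)
  expect_equal(same$h, matrix(1 / 3, 2, 3), tolerance = 1e-12)
  expect_equal(same$v, e1, tolerance = 1e-12)

  single <- attention(list(e1), params)
  expect_equal(single$h, matrix(1, 2, 1))
  expect_equal(single$v, e1)
})

test_that("analytic gradients match finite differences through the whole branch", {
  set.seed(62)
  cfg <- classical_branch_config(hidden_size = 3, num_layers = 2,
                                 hidden_linear_size = 5, lstm_dropout = 0,
                                 linear_dropout = 0, seed = 1)
  params <- ieegfuse:::classical_init(4, cfg)
  xs <- lapply(1:3, function(t) matrix(rnorm(2 * 4), 2, 4))
  y <- c(1, 0)
  fwd <- ieegfuse:::classical_forward(params, xs, cfg, training = FALSE)
  gr <- ieegfuse:::classical_backward(params, fwd, y, cfg)
  loss_at <- function(p) {
    bce_loss(y, ieegfuse:::classical_forward(p, xs, cfg, training = FALSE)$p)
  }
  eps <- 1e-6
  checks <- list(
    list(g = gr$layers[[1]]$fwd$Wx[1, 1],
         set = function(p, v) { p$layers[[1]]$fwd$Wx[1, 1] <- v; p },
         get = function(p) p$layers[[1]]$fwd$Wx[1, 1]),
    list(g = gr$layers[[2]]$bwd$Wh[2, 3],
         set = function(p, v) { p$layers[[2]]$bwd$Wh[2, 3] <- v; p },
         get = function(p) p$layers[[2]]$bwd$Wh[2, 3]),
    list(g = gr$att$Ww[1, 2],
         set = function(p, v) { p$att$Ww[1, 2] <- v; p },
         get = function(p) p$att$Ww[1, 2]),
    list(g = gr$att$uw[3, 1],
         set = function(p, v) { p$att$uw[3, 1] <- v; p },
         get = function(p) p$att$uw[3, 1]),
    list(g = gr$fc2$b[1, 1],
         set = function(p, v) { p$fc2$b[1, 1] <- v; p },
         get = function(p) p$fc2$b[1, 1]))
  for (ck in checks) {
    num <- (loss_at(ck$set(params, ck$get(params) + eps)) -
              loss_at(ck$set(params, ck$get(params) - eps))) / (2 * eps)
    expect_lt(abs(ck$g - num), 1e-7 + 1e-4 * abs(num))
  }
})

test_that("branch forward yields a 128-d embedding and valid probabilities", {
  set.seed(63)
  cfg <- classical_branch_config(seed = 2)
  params <- ieegfuse:::classical_init(70, cfg)
  xs <- lapply(1:4, function(t) matrix(rnorm(5 * 70), 5, 70))
  fwd <- ieegfuse:::classical_forward(params, xs, cfg, training = FALSE)
  expect_equal(ncol(fwd$v), 128)          # 2 x hidden_size 64
  expect_true(all(fwd$p > 0 & fwd$p < 1))
  fwd2 <- ieegfuse:::classical_forward(params, xs, cfg, training = FALSE)
  expect_identical(fwd$p, fwd2$p)          # eval mode is deterministic
})

test_that("training rejects degenerate inputs", {
  x <- array(rnorm(10 * 2 * 70), dim = c(10, 2, 70))
  expect_error(train_classical(x, rep(1, 10), x, rep(1, 10)), "both classes")
  x_bad <- x
  x_bad[1, 1, 1] <- NaN
  expect_error(train_classical(x_bad, rep(c(0, 1), 5), x, rep(c(0, 1), 5)),
               "non-finite")
})

test_that("the branch can overfit a tiny batch and starts near chance", {
  set.seed(64)
  x <- array(rnorm(20 * 4 * 10), dim = c(20, 4, 10))
  y <- rep(c(0, 1), 10)
  x[y == 1, , 1] <- x[y == 1, , 1] + 2
  cfg <- classical_branch_config(hidden_size = 8, hidden_linear_size = 16,
                                 batch_size = 20, epochs = 50, seed = 3, lr = 1e-2,
                                 lstm_dropout = 0, linear_dropout = 0)
  fit <- train_classical(x, y, x, y, cfg)
  expect_lte(fit$history$train_loss[1], log(2) + 0.2)  # near ln 2 at the start
  expect_lt(min(fit$history$train_loss), 0.1)          # capacity smoke test

  fit2 <- train_classical(x, y, x, y, cfg)
  expect_identical(fit$history, fit2$history)          # seeded determinism
})
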