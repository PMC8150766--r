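test_that("fusion concatenates classical-first into a 256-vector", {
  a <- matrix(rnorm(3 * 128), 3)
  b <- matrix(rnorm(3 * 128), 3)
  f <- fuse(a, b)
  expect_equal(dim(f), c(3, 256))
  expect_equal(f[, 1:128], a)
  expect_equal(f[, 129:256], b)

  z <- fuse(rep(0, 128), rnorm(128))
  expect_true(all(z[1, 1:128] == 0))
  expect_false(isTRUE(all.equal(fuse(a, b), fuse(b, a))))  # order is stable

  expect_error(fuse(matrix(0, 1, 64), matrix(0, 1, 128)), "128")
  expect_error(fuse(matrix(NaN, 1, 128), matrix(0, 1, 128)), "finite")
})

test_that("binary cross-entropy matches its closed form on a grid", {
  expect_lt(bce_loss(1, 1), 1e-6)
  expect_equal(bce_loss(1, 0.5), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(0, 0.9), -log(0.1), tolerance = 1e-12)
  for (y in c(0, 1)) {
    for (p in c(0.05, 0.2, 0.5, 0.77, 0.95)) {
      expect_equal(bce_loss(y, p), -(y * log(p) + (1 - y) * log(1 - p)),
                   tolerance = 1e-12)
    }
  }
  expect_gte(bce_loss(1, 0), 0)  # clipped, finite
  expect_true(is.finite(bce_loss(1, 0)))
})

test_that("fusion training freezes branch weights and beats chance", {
  set.seed(80)
  n <- 40
  y <- rep(c(0, 1), n / 2)
  seq_x <- array(rnorm(n * 2 * 10), dim = c(n, 2, 10))
  seq_x[y == 1, , 1] <- seq_x[y == 1, , 1] + 2
  sig_x <- matrix(rnorm(n * 128), n, 128)
  sig_x[y == 1, 60:64] <- sig_x[y == 1, 60:64] + 3

  cl <- train_classical(seq_x, y, seq_x, y,
                        classical_branch_config(hidden_linear_size = 16,
                                                epochs = 20, seed = 5,
                                                lstm_dropout = 0, linear_dropout = 0))
  cn <- train_cnn(sig_x, y, sig_x, y, cnn_config(epochs = 10, seed = 6))
  snap_cl <- cl$params
  snap_cn <- cn$params
  fu <- train_fusion(cl, cn, seq_x, sig_x, y, seq_x, sig_x, y,
                     fusion_config(epochs = 30, seed = 7))
  expect_identical(fu$classical$params, snap_cl)  # freezing contract
  expect_identical(fu$cnn$params, snap_cn)
  expect_gt(fu$val_acc, 0.5)

  fu2 <- train_fusion(cl, cn, seq_x, sig_x, y, seq_x, sig_x, y,
                      fusion_config(epochs = 30, seed = 7))
  expect_identical(fu$history, fu2$history)       # seeded determinism

  expect_error(train_fusion(cl, list(), seq_x, sig_x, y, seq_x, sig_x, y),
               "trained")
})

test_that("pipeline prediction is deterministic with the documented tie-break", {
  set.seed(81)
  n <- 20
  y <- rep(c(0, 1), n / 2)
  seq_x <- array(rnorm(n * 2 * 10), dim = c(n, 2, 10))
  seq_x[y == 1, , 1] <- seq_x[y == 1, , 1] + 2
  sig_x <- matrix(rnorm(n * 128), n, 128)
  cl <- train_classical(seq_x, y, seq_x, y,
                        classical_branch_config(hidden_linear_size = 8,
                                                epochs = 5, seed = 8,
                                                lstm_dropout = 0, linear_dropout = 0))
  cn <- train_cnn(sig_x, y, sig_x, y, cnn_config(epochs = 2, seed = 9))
  fu <- train_fusion(cl, cn, seq_x, sig_x, y, seq_x, sig_x, y,
                     fusion_config(epochs = 5, seed = 10))
  pred1 <- predict_fusion(fu, seq_x, sig_x)
  pred2 <- predict_fusion(fu, seq_x, sig_x)
  expect_identical(pred1, pred2)
  expect_equal(dim(attr(pred1, "fusion_features")), c(n, 256))
  expect_true(all(pred1$probability > 0 & pred1$probability < 1))
  expect_true(all(pred1$label %in% c("ES", "NES")))
  # the >= 0.5 rule maps an exact tie to ES
  expect_equal(ifelse(0.5 >= 0.5, "ES", "NES"), "ES")
  expect_true(all((pred1$probability >= 0.5) == (pred1$label == "ES")))
})

test_that("model checkpoints round-trip with a config fingerprint", {
  set.seed(82)
  x <- array(rnorm(8 * 2 * 5), dim = c(8, 2, 5))
  y <- rep(c(0, 1), 4)
  cl <- train_classical(x, y, x, y,
                        classical_branch_config(hidden_size = 3,
                                                hidden_linear_size = 4,
                                                epochs = 2, seed = 11,
                                                lstm_dropout = 0, linear_dropout = 0))
  path <- tempfile(fileext = ".rds")
  save_model(cl, path)
  back <- load_model(path)
  expect_identical(back$params, cl$params)

  corrupt <- cl
  corrupt$fingerprint <- "tampered"
  save_model(corrupt, path)
  expect_error(load_model(path), "fingerprint")
})
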