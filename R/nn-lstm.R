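#' Configuration of the Bi-LSTM-attention branch
#'
#' Defaults follow the published training setup: hidden size 64 per
#' direction, 2 stacked bidirectional layers with inter-layer dropout 0.1,
#' a 256-unit post-attention linear layer with dropout 0.3, batch size 20,
#' 100 epochs, Adam.
#'
#' @param hidden_size LSTM hidden units per direction.
#' @param num_layers stacked bidirectional layers.
#' @param lstm_dropout dropout between LSTM layers.
#' @param hidden_linear_size width of the post-attention linear layer.
#' @param linear_dropout dropout before the output unit.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @return A `classical_branch_config` list.
#' @export
classical_branch_config <- function(hidden_size = 64, num_layers = 2,
                                    lstm_dropout = 0.1,
                                    hidden_linear_size = 256,
                                    linear_dropout = 0.3, batch_size = 20,
                                    epochs = 100, lr = 1e-3, seed = 1L) {
  structure(as.list(environment()), class = "classical_branch_config")
}

# ---- LSTM cell -------------------------------------------------------------

lstm_layer_init <- function(n_in, hidden) {
  list(Wx = nn_uniform_init(n_in, 4 * hidden, fan_in = hidden),
       Wh = nn_uniform_init(hidden, 4 * hidden, fan_in = hidden),
       b = matrix(runif(4 * hidden, -1 / sqrt(hidden), 1 / sqrt(hidden)), 1))
}

# one step; gates ordered i, f, g, o. x: B x n_in; h, c: B x H
lstm_cell_forward <- function(p, x, h, c) {
  H <- ncol(h)
  z <- x %*% p$Wx + h %*% p$Wh
  z <- sweep(z, 2, p$b, `+`)
  i <- sigmoid(z[, 1:H, drop = FALSE])
  f <- sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
  g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
  o <- sigmoid(z[, (3 * H + 1):(4 * H), drop = FALSE])
  c_new <- f * c + i * g
  h_new <- o * tanh(c_new)
  list(h = h_new, c = c_new,
       cache = list(x = x, h_prev = h, c_prev = c, i = i, f = f, g = g, o = o,
                    c_new = c_new))
}

lstm_cell_backward <- function(p, cache, dh, dc) {
  tc <- tanh(cache$c_new)
  do_ <- dh * tc
  dc_total <- dc + dh * cache$o * (1 - tc^2)
  di <- dc_total * cache$g
  df <- dc_total * cache$c_prev
  dg <- dc_total * cache$i
  dc_prev <- dc_total * cache$f
  dz <- cbind(di * cache$i * (1 - cache$i),
              df * cache$f * (1 - cache$f),
              dg * (1 - cache$g^2),
              do_ * cache$o * (1 - cache$o))
  list(dx = dz %*% t(p$Wx),
       dh_prev = dz %*% t(p$Wh),
       dc_prev = dc_prev,
       grads = list(Wx = t(cache$x) %*% dz, Wh = t(cache$h_prev) %*% dz,
                    b = matrix(colSums(dz), 1)))
}

# run one direction over the sequence. xs: list of T matrices (B x n_in)
lstm_run <- function(p, xs, reverse = FALSE) {
  T_ <- length(xs)
  B <- nrow(xs[[1]])
  H <- nrow(p$Wh)
  h <- matrix(0, B, H)
  c <- h
  order_t <- if (reverse) rev(seq_len(T_)) else seq_len(T_)
  hs <- vector("list", T_)
  caches <- vector("list", T_)
  for (t in order_t) {
    st <- lstm_cell_forward(p, xs[[t]], h, c)
    h <- st$h; c <- st$c
    hs[[t]] <- h
    caches[[t]] <- st$cache
  }
  list(hs = hs, caches = caches, order = order_t)
}

lstm_run_backward <- function(p, run, dhs) {
  T_ <- length(dhs)
  B <- nrow(dhs[[1]])
  H <- ncol(dhs[[1]])
  grads <- tree_zeros(p)
  dxs <- vector("list", T_)
  dh_next <- matrix(0, B, H)
  dc_next <- matrix(0, B, H)
  for (t in rev(run$order)) {
    bk <- lstm_cell_backward(p, run$caches[[t]], dhs[[t]] + dh_next, dc_next)
    dxs[[t]] <- bk$dx
    dh_next <- bk$dh_prev
    dc_next <- bk$dc_prev
    grads <- tree_map2(grads, bk$grads, `+`)
  }
  list(dxs = dxs, grads = grads)
}

# ---- attention (additive, context-vector scored) ---------------------------

attention_init <- function(dim) {
  list(Ww = nn_uniform_init(dim, dim), bw = matrix(runif(dim, -1 / sqrt(dim), 1 / sqrt(dim)), 1),
       uw = nn_uniform_init(dim, 1))
}

#' Additive attention pooling
#'
#' `u_t = tanh(Ww e_t + bw)`, `h_t = softmax_t(u_t' uw)`,
#' `v = sum_t h_t e_t`. The weights form a probability distribution over
#' timesteps.
#'
#' @param e list of `T` matrices (batch x dim), the encoder outputs.
#' @param params list with `Ww` (dim x dim), `bw` (1 x dim), `uw` (dim x 1).
#' @return List with `v` (batch x dim), `h` (batch x T weights) and a
#'   backward cache.
#' @export
attention <- function(e, params) {
  T_ <- length(e)
  scores <- matrix(0, nrow(e[[1]]), T_)
  us <- vector("list", T_)
  for (t in seq_len(T_)) {
    u <- tanh(sweep(e[[t]] %*% params$Ww, 2, params$bw, `+`))
    us[[t]] <- u
    scores[, t] <- u %*% params$uw
  }
  sm <- exp(scores - apply(scores, 1, max))
  h <- sm / rowSums(sm)
  v <- matrix(0, nrow(h), ncol(e[[1]]))
  for (t in seq_len(T_)) v <- v + h[, t] * e[[t]]
  list(v = v, h = h, cache = list(e = e, us = us))
}

attention_backward <- function(params, out, dv, dh_extra = NULL) {
  e <- out$cache$e; us <- out$cache$us; h <- out$h
  T_ <- length(e)
  B <- nrow(dv)
  des <- vector("list", T_)
  dscore <- matrix(0, B, T_)
  for (t in seq_len(T_)) {
    dscore[, t] <- rowSums(dv * e[[t]])
    des[[t]] <- h[, t] * dv
  }
  if (!is.null(dh_extra)) dscore <- dscore + dh_extra
  # softmax backward per row
  dsc <- h * (dscore - rowSums(dscore * h))
  grads <- tree_zeros(params)
  for (t in seq_len(T_)) {
    du <- matrix(dsc[, t], B, 1) %*% t(params$uw)
    dpre <- du * (1 - us[[t]]^2)
    grads$Ww <- grads$Ww + t(e[[t]]) %*% dpre
    grads$bw <- grads$bw + matrix(colSums(dpre), 1)
    grads$uw <- grads$uw + t(us[[t]]) %*% matrix(dsc[, t], B, 1)
    des[[t]] <- des[[t]] + dpre %*% t(params$Ww)
  }
  list(des = des, grads = grads)
}

# ---- full branch -----------------------------------------------------------

classical_init <- function(n_features, cfg) {
  H <- cfg$hidden_size
  layers <- vector("list", cfg$num_layers)
  for (l in seq_len(cfg$num_layers)) {
    n_in <- if (l == 1) n_features else 2 * H
    layers[[l]] <- list(fwd = lstm_layer_init(n_in, H),
                        bwd = lstm_layer_init(n_in, H))
  }
  list(layers = layers,
       att = attention_init(2 * H),
       fc1 = dense_init(2 * H, cfg$hidden_linear_size),
       fc2 = dense_init(cfg$hidden_linear_size, 1))
}

# xs: list of T matrices (B x F). Returns p, embedding v (B x 128), caches.
classical_forward <- function(params, xs, cfg, training = FALSE) {
  caches <- list(drop = list(), runs = list())
  inp <- xs
  for (l in seq_along(params$layers)) {
    pf <- params$layers[[l]]
    rf <- lstm_run(pf$fwd, inp, reverse = FALSE)
    rb <- lstm_run(pf$bwd, inp, reverse = TRUE)
    out <- mapply(function(a, b) cbind(a, b), rf$hs, rb$hs, SIMPLIFY = FALSE)
    if (l < length(params$layers)) {
      dr <- lapply(out, dropout_forward, rate = cfg$lstm_dropout, training = training)
      out <- lapply(dr, `[[`, "out")
      caches$drop[[l]] <- lapply(dr, `[[`, "mask")
    }
    caches$runs[[l]] <- list(f = rf, b = rb)
    inp <- out
  }
  att <- attention(inp, params$att)
  f1 <- dense_forward(params$fc1, att$v)
  r1 <- relu_forward(f1$out)
  d1 <- dropout_forward(r1$out, cfg$linear_dropout, training)
  f2 <- dense_forward(params$fc2, d1$out)
  p <- sigmoid(f2$out)
  list(p = as.numeric(p), v = att$v, h_att = att$h,
       caches = list(lstm = caches, att = att, f1 = f1, r1 = r1, d1 = d1,
                     f2 = f2, p = p, enc = inp))
}

classical_backward <- function(params, fwd, y, cfg) {
  ca <- fwd$caches
  dp <- matrix(bce_grad(y, as.numeric(ca$p)), ncol = 1)
  dz2 <- dp * ca$p * (1 - ca$p)
  b2 <- dense_backward(params$fc2, ca$f2, dz2)
  dd1 <- dropout_backward(ca$d1, b2$dx)
  dr1 <- relu_backward(ca$r1, dd1)
  b1 <- dense_backward(params$fc1, ca$f1, dr1)
  att_bk <- attention_backward(params$att, ca$att, b1$dx)
  grads <- list(layers = vector("list", length(params$layers)),
                att = att_bk$grads, fc1 = b1$grads, fc2 = b2$grads)
  dout <- att_bk$des
  for (l in rev(seq_along(params$layers))) {
    if (l < length(params$layers)) {
      masks <- ca$lstm$drop[[l]]
      dout <- mapply(function(d, m) if (is.null(m)) d else d * m,
                     dout, masks, SIMPLIFY = FALSE)
    }
    H <- cfg$hidden_size
    d_f <- lapply(dout, function(d) d[, 1:H, drop = FALSE])
    d_b <- lapply(dout, function(d) d[, (H + 1):(2 * H), drop = FALSE])
    run <- ca$lstm$runs[[l]]
    bf <- lstm_run_backward(params$layers[[l]]$fwd, run$f, d_f)
    bb <- lstm_run_backward(params$layers[[l]]$bwd, run$b, d_b)
    grads$layers[[l]] <- list(fwd = bf$grads, bwd = bb$grads)
    dout <- mapply(`+`, bf$dxs, bb$dxs, SIMPLIFY = FALSE)
  }
  grads
}

# standardization helper: mu/sd per feature over (N*T) rows
standardizer_fit <- function(x_mat) {
  mu <- colMeans(x_mat)
  s <- apply(x_mat, 2, sd)
  s[s == 0 | !is.finite(s)] <- 1
  list(mu = mu, sd = s)
}

standardize_seq_array <- function(arr, sc) {
  # arr: N x T x F
  for (f in seq_len(dim(arr)[3])) {
    arr[, , f] <- (arr[, , f] - sc$mu[f]) / sc$sd[f]
  }
  arr
}

seq_array_to_batchlist <- function(arr, idx) {
  T_ <- dim(arr)[2]
  lapply(seq_len(T_), function(t) matrix(arr[idx, t, ], nrow = length(idx)))
}

#' Train the Bi-LSTM-attention branch
#'
#' Minimizes binary cross-entropy with Adam over minibatches; per-feature
#' standardization statistics are fit on the training set and stored with
#' the model. The best-on-validation-accuracy weights are kept.
#'
#' @param x_train,x_val numeric arrays `N x T x 70` of feature sequences.
#' @param y_train,y_val labels in `{0, 1}` (1 = ES).
#' @param cfg a [classical_branch_config()].
#' @return A `classical_branch` model: parameters, scaler, config and a
#'   per-epoch history tibble (`epoch`, `train_loss`, `val_loss`, `val_acc`).
#' @export
train_classical <- function(x_train, y_train, x_val, y_val,
                            cfg = classical_branch_config()) {
  if (length(unique(y_train)) < 2) abort("training set must contain both classes")
  if (any(!is.finite(x_train))) abort("non-finite feature values in training input")
  with_seed(cfg$seed, {
    sc <- standardizer_fit(apply(x_train, 3, c))
    xt <- standardize_seq_array(x_train, sc)
    xv <- standardize_seq_array(x_val, sc)
    params <- classical_init(dim(x_train)[3], cfg)
    opt <- adam_init(params)
    best <- list(acc = -1, params = params)
    hist <- vector("list", cfg$epochs)
    n <- dim(xt)[1]
    for (ep in seq_len(cfg$epochs)) {
      losses <- c()
      for (bi in make_batches(n, cfg$batch_size)) {
        xs <- seq_array_to_batchlist(xt, bi)
        fwd <- classical_forward(params, xs, cfg, training = TRUE)
        losses <- c(losses, bce_loss(y_train[bi], fwd$p))
        grads <- classical_backward(params, fwd, y_train[bi], cfg)
        st <- adam_step(params, grads, opt, lr = cfg$lr)
        params <- st$params; opt <- st$state
      }
      vf <- classical_forward(params, seq_array_to_batchlist(xv, seq_len(dim(xv)[1])),
                              cfg, training = FALSE)
      val_loss <- bce_loss(y_val, vf$p)
      val_acc <- prob_accuracy(y_val, vf$p)
      if (val_acc > best$acc) best <- list(acc = val_acc, params = params)
      hist[[ep]] <- tibble::tibble(epoch = ep, train_loss = mean(losses),
                                   val_loss = val_loss, val_acc = val_acc)
    }
    structure(list(params = best$params, scaler = sc, config = cfg,
                   history = bind_rows(hist), val_acc = best$acc,
                   fingerprint = config_fingerprint(cfg)),
              class = "classical_branch")
  })
}

#' Classical-branch inference
#'
#' @param model a trained `classical_branch`.
#' @param x array `N x T x 70` of feature sequences.
#' @return List with `p` (probabilities), `embedding` (`N x 128` attention
#'   outputs) and `h_att` (`N x T` attention weights).
#' @export
classical_predict <- function(model, x) {
  xs <- seq_array_to_batchlist(standardize_seq_array(x, model$scaler),
                               seq_len(dim(x)[1]))
  fwd <- classical_forward(model$params, xs, model$config, training = FALSE)
  list(p = fwd$p, embedding = fwd$v, h_att = fwd$h_att)
}

config_fingerprint <- function(cfg) {
  paste(names(cfg), vapply(cfg, function(v) paste(format(v), collapse = "/"), ""),
        sep = "=", collapse = ";")
}
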