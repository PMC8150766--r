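#' Configuration of the 1D-CNN branch
#'
#' Four convolution blocks, each convolution + batch normalization + ReLU +
#' max pooling (size 2), with (in, out, kernel, stride, padding) =
#' (1,16,3,1,1), (16,32,3,1,1), (32,32,3,1,1), (32,32,2,1,1); an adaptive
#' max-pool to 4 positions per channel yields the fixed 32 x 4 = 128
#' automatic embedding for any input length, followed by a 128 -> 64 -> 1
#' sigmoid head. Batch size 32, 100 epochs, Adam.
#'
#' @param conv_layers list of `c(in, out, kernel, stride, padding)` per block.
#' @param pool_size max-pool window per block.
#' @param embed_len adaptive-pool target positions per channel.
#' @param batch_size,epochs,lr,seed training knobs.
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(conv_layers = list(c(1, 16, 3, 1, 1), c(16, 32, 3, 1, 1),
                                          c(32, 32, 3, 1, 1), c(32, 32, 2, 1, 1)),
                       pool_size = 2, embed_len = 4, batch_size = 32,
                       epochs = 100, lr = 1e-3, seed = 1L) {
  structure(as.list(environment()), class = "cnn_config")
}

# ---- conv / bn / pool primitives (x is B x L x C arrays) -------------------

conv1d_init <- function(c_in, c_out, k) {
  fan <- c_in * k
  list(W = array(runif(k * c_in * c_out, -1 / sqrt(fan), 1 / sqrt(fan)),
                 dim = c(k, c_in, c_out)),
       b = matrix(runif(c_out, -1 / sqrt(fan), 1 / sqrt(fan)), 1))
}

pad_x <- function(x, pad) {
  if (pad == 0) return(x)
  d <- dim(x)
  xp <- array(0, dim = c(d[1], d[2] + 2 * pad, d[3]))
  xp[, (pad + 1):(pad + d[2]), ] <- x
  xp
}

conv1d_forward <- function(p, x, stride = 1, pad = 1) {
  xp <- pad_x(x, pad)
  d <- dim(xp); B <- d[1]; Lp <- d[2]; Cin <- d[3]
  k <- dim(p$W)[1]; Cout <- dim(p$W)[3]
  Lout <- (Lp - k) %/% stride + 1
  pos <- seq(1, by = stride, length.out = Lout)
  out_mat <- matrix(rep(as.numeric(p$b), each = B * Lout), B * Lout, Cout)
  for (j in seq_len(k)) {
    xj <- xp[, pos + j - 1, , drop = FALSE]
    dim(xj) <- c(B * Lout, Cin)
    Wj <- p$W[j, , ]
    dim(Wj) <- c(Cin, Cout)
    out_mat <- out_mat + xj %*% Wj
  }
  list(out = array(out_mat, dim = c(B, Lout, Cout)),
       cache = list(xp = xp, pos = pos, pad = pad, Lin = d[2] - 2 * pad,
                    stride = stride))
}

conv1d_backward <- function(p, cache, dout) {
  d <- dim(dout); B <- d[1]; Lout <- d[2]; Cout <- d[3]
  k <- dim(p$W)[1]; Cin <- dim(p$W)[2]
  dmat <- matrix(dout, B * Lout, Cout)
  dW <- array(0, dim = dim(p$W))
  dxp <- array(0, dim = dim(cache$xp))
  for (j in seq_len(k)) {
    xj <- cache$xp[, cache$pos + j - 1, , drop = FALSE]
    dim(xj) <- c(B * Lout, Cin)
    dW[j, , ] <- t(xj) %*% dmat
    Wj <- p$W[j, , ]
    dim(Wj) <- c(Cin, Cout)
    dxj <- dmat %*% t(Wj)
    dim(dxj) <- c(B, Lout, Cin)
    # scatter-add back (stride 1 positions may overlap across j)
    dxp[, cache$pos + j - 1, ] <- dxp[, cache$pos + j - 1, , drop = FALSE] + dxj
  }
  pad <- cache$pad
  dx <- if (pad > 0) dxp[, (pad + 1):(pad + cache$Lin), , drop = FALSE] else dxp
  list(dx = dx, grads = list(W = dW, b = matrix(colSums(dmat), 1)))
}

bn_init <- function(c_out) {
  list(gamma = matrix(1, 1, c_out), beta = matrix(0, 1, c_out))
}

bn_forward <- function(p, x, state, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  xm <- matrix(x, d[1] * d[2], d[3])
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(sweep(xm, 2, mu)^2)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
  } else {
    mu <- state$mean; v <- state$var
  }
  n <- d[1] * d[2]
  xhat <- (xm - rep(mu, each = n)) * rep(1 / sqrt(v + eps), each = n)
  out <- xhat * rep(as.numeric(p$gamma), each = n) + rep(as.numeric(p$beta), each = n)
  dim(out) <- d
  list(out = out, state = state,
       cache = list(xhat = xhat, invstd = 1 / sqrt(v + eps), d = d,
                    training = training))
}

bn_backward <- function(p, cache, dout) {
  d <- cache$d
  n <- d[1] * d[2]
  dmat <- matrix(dout, n, d[3])
  dgamma <- matrix(colSums(dmat * cache$xhat), 1)
  dbeta <- matrix(colSums(dmat), 1)
  dxhat <- dmat * rep(as.numeric(p$gamma), each = n)
  if (cache$training) {
    dx <- (dxhat - rep(colMeans(dxhat), each = n) -
             cache$xhat * rep(colMeans(dxhat * cache$xhat), each = n)) *
      rep(cache$invstd, each = n)
  } else {
    dx <- dxhat * rep(cache$invstd, each = n)
  }
  dim(dx) <- d
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

maxpool_forward <- function(x, size = 2) {
  d <- dim(x)
  Lout <- d[2] %/% size
  out <- x[, seq(1, by = size, length.out = Lout), , drop = FALSE]
  amax <- array(1L, dim = dim(out))
  if (size > 1) {
    for (j in 2:size) {
      cand <- x[, seq(j, by = size, length.out = Lout), , drop = FALSE]
      better <- cand > out
      out[better] <- cand[better]
      amax[better] <- j
    }
  }
  list(out = out, cache = list(amax = amax, size = size, d_in = d))
}

maxpool_backward <- function(cache, dout) {
  d <- cache$d_in
  size <- cache$size
  Lout <- dim(dout)[2]
  dx <- array(0, dim = d)
  # linear index arithmetic into the (B, size, Lout, C) view
  B <- d[1]; C <- d[3]
  bi <- rep(seq_len(B), times = Lout * C)
  li <- rep(rep(seq_len(Lout), each = B), times = C)
  ci <- rep(seq_len(C), each = B * Lout)
  pos_in <- (li - 1) * size + as.vector(cache$amax)
  dx[cbind(bi, pos_in, ci)] <- as.vector(dout)
  dx
}

# adaptive max pool to `target` positions per channel (contiguous bins)
adaptive_maxpool_forward <- function(x, target) {
  d <- dim(x)
  L <- d[2]
  out <- array(0, dim = c(d[1], target, d[3]))
  amax <- array(0L, dim = c(d[1], target, d[3]))
  for (t in seq_len(target)) {
    lo <- floor((t - 1) * L / target) + 1
    hi <- max(lo, ceiling(t * L / target))
    best <- x[, lo, , drop = FALSE]
    arg <- array(lo, dim = dim(best))
    if (hi > lo) {
      for (j in (lo + 1):hi) {
        cand <- x[, j, , drop = FALSE]
        better <- cand > best
        best[better] <- cand[better]
        arg[better] <- j
      }
    }
    out[, t, ] <- best
    amax[, t, ] <- arg
  }
  list(out = out, cache = list(amax = amax, d_in = d))
}

adaptive_maxpool_backward <- function(cache, dout) {
  d <- cache$d_in
  dx <- array(0, dim = d)
  B <- d[1]; target <- dim(dout)[2]; C <- d[3]
  bi <- rep(seq_len(B), times = target * C)
  ci <- rep(seq_len(C), each = B * target)
  dx[cbind(bi, as.vector(cache$amax), ci)] <- as.vector(dout)
  dx
}

# ---- full branch -----------------------------------------------------------

cnn_init <- function(cfg) {
  blocks <- lapply(cfg$conv_layers, function(cl) {
    list(conv = conv1d_init(cl[1], cl[2], cl[3]), bn = bn_init(cl[2]))
  })
  c_last <- cfg$conv_layers[[length(cfg$conv_layers)]][2]
  list(blocks = blocks,
       fc1 = dense_init(c_last * cfg$embed_len, 64),
       fc2 = dense_init(64, 1))
}

cnn_state_init <- function(cfg) {
  lapply(cfg$conv_layers, function(cl) list(mean = numeric(cl[2]), var = rep(1, cl[2])))
}

cnn_forward <- function(params, x, cfg, state, training = FALSE) {
  # x: B x L matrix -> B x L x 1 array
  a <- array(x, dim = c(nrow(x), ncol(x), 1))
  caches <- vector("list", length(params$blocks))
  for (l in seq_along(params$blocks)) {
    cl <- cfg$conv_layers[[l]]
    cv <- conv1d_forward(params$blocks[[l]]$conv, a, stride = cl[4], pad = cl[5])
    bn <- bn_forward(params$blocks[[l]]$bn, cv$out, state[[l]], training)
    state[[l]] <- bn$state
    rl <- relu_forward(bn$out)
    mp <- maxpool_forward(rl$out, cfg$pool_size)
    caches[[l]] <- list(cv = cv, bn = bn, rl = rl, mp = mp)
    a <- mp$out
  }
  ap <- adaptive_maxpool_forward(a, cfg$embed_len)
  B <- dim(ap$out)[1]
  emb <- aperm(ap$out, c(1, 3, 2))
  dim(emb) <- c(B, prod(dim(ap$out)[2:3]))  # B x (C * embed_len)
  f1 <- dense_forward(params$fc1, emb)
  r1 <- relu_forward(f1$out)
  f2 <- dense_forward(params$fc2, r1$out)
  p <- sigmoid(f2$out)
  list(p = as.numeric(p), embedding = emb, state = state,
       caches = list(blocks = caches, ap = ap, f1 = f1, r1 = r1, f2 = f2,
                     p = p, emb_dim = dim(ap$out)))
}

cnn_backward <- function(params, fwd, y, cfg) {
  ca <- fwd$caches
  dp <- matrix(bce_grad(y, as.numeric(ca$p)), ncol = 1)
  dz2 <- dp * ca$p * (1 - ca$p)
  b2 <- dense_backward(params$fc2, ca$f2, dz2)
  dr1 <- relu_backward(ca$r1, b2$dx)
  b1 <- dense_backward(params$fc1, ca$f1, dr1)
  demb <- aperm(array(b1$dx, dim = ca$emb_dim[c(1, 3, 2)]), c(1, 3, 2))
  da <- adaptive_maxpool_backward(ca$ap$cache, demb)
  grads <- list(blocks = vector("list", length(params$blocks)),
                fc1 = b1$grads, fc2 = b2$grads)
  for (l in rev(seq_along(params$blocks))) {
    blk <- ca$blocks[[l]]
    dmp <- maxpool_backward(blk$mp$cache, da)
    drl <- relu_backward(blk$rl, dmp)
    dbn <- bn_backward(params$blocks[[l]]$bn, blk$bn$cache, drl)
    dcv <- conv1d_backward(params$blocks[[l]]$conv, blk$cv$cache, dbn$dx)
    grads$blocks[[l]] <- list(conv = dcv$grads, bn = dbn$grads)
    da <- dcv$dx
  }
  grads
}

#' Train the 1D-CNN branch
#'
#' End-to-end training on raw (preprocessed) single-channel segments;
#' dual-channel inputs are averaged to one channel. Inputs are globally
#' standardized with training-set statistics. Best-on-validation-accuracy
#' weights (and their batch-norm running statistics) are kept.
#'
#' @param x_train,x_val numeric matrices `N x L` of segment samples.
#' @param y_train,y_val labels in `{0, 1}` (1 = ES).
#' @param cfg a [cnn_config()].
#' @return A `cnn_branch` model with parameters, batch-norm state, scaler,
#'   config and history tibble.
#' @export
train_cnn <- function(x_train, y_train, x_val, y_val, cfg = cnn_config()) {
  if (length(unique(y_train)) < 2) abort("training set must contain both classes")
  if (ncol(x_train) < 16) abort("segments too short for the four-block CNN")
  with_seed(cfg$seed, {
    mu <- mean(x_train); s <- sd(x_train); if (s == 0) s <- 1
    xt <- (x_train - mu) / s
    xv <- (x_val - mu) / s
    params <- cnn_init(cfg)
    state <- cnn_state_init(cfg)
    opt <- adam_init(params)
    best <- list(acc = -1, params = params, state = state)
    hist <- vector("list", cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      losses <- c()
      for (bi in make_batches(nrow(xt), cfg$batch_size)) {
        fwd <- cnn_forward(params, xt[bi, , drop = FALSE], cfg, state, training = TRUE)
        state <- fwd$state
        losses <- c(losses, bce_loss(y_train[bi], fwd$p))
        grads <- cnn_backward(params, fwd, y_train[bi], cfg)
        st <- adam_step(params, grads, opt, lr = cfg$lr)
        params <- st$params; opt <- st$state
      }
      vf <- cnn_forward(params, xv, cfg, state, training = FALSE)
      val_loss <- bce_loss(y_val, vf$p)
      val_acc <- prob_accuracy(y_val, vf$p)
      if (val_acc > best$acc) best <- list(acc = val_acc, params = params, state = state)
      hist[[ep]] <- tibble::tibble(epoch = ep, train_loss = mean(losses),
                                   val_loss = val_loss, val_acc = val_acc)
    }
    structure(list(params = best$params, bn_state = best$state,
                   scaler = list(mu = mu, sd = s), config = cfg,
                   history = bind_rows(hist), val_acc = best$acc,
                   fingerprint = config_fingerprint(cfg)),
              class = "cnn_branch")
  })
}

#' CNN-branch inference
#'
#' @param model a trained `cnn_branch`.
#' @param x matrix `N x L` of segment samples.
#' @return List with `p` (probabilities) and `embedding` (`N x 128`).
#' @export
cnn_predict <- function(model, x) {
  xs <- (x - model$scaler$mu) / model$scaler$sd
  fwd <- cnn_forward(model$params, xs, model$config, model$bn_state, training = FALSE)
  list(p = fwd$p, embedding = fwd$embedding)
}

#' Per-channel activation maps at a convolution block
#'
#' Returns the post-ReLU activations of the chosen block for one segment,
#' for inspection or plotting of what the filters respond to.
#'
#' @param model a trained `cnn_branch`.
#' @param x numeric vector, one segment's samples.
#' @param layer block index 1..4.
#' @return Tibble with `channel`, `position`, `activation`.
#' @export
activation_maps <- function(model, x, layer = 1) {
  cfg <- model$config
  if (!layer %in% seq_along(cfg$conv_layers)) abort("invalid layer index")
  xs <- matrix((x - model$scaler$mu) / model$scaler$sd, nrow = 1)
  a <- array(xs, dim = c(1, length(x), 1))
  state <- model$bn_state
  for (l in seq_len(layer)) {
    cl <- cfg$conv_layers[[l]]
    cv <- conv1d_forward(model$params$blocks[[l]]$conv, a, stride = cl[4], pad = cl[5])
    bn <- bn_forward(model$params$blocks[[l]]$bn, cv$out, state[[l]], training = FALSE)
    rl <- relu_forward(bn$out)
    mp <- maxpool_forward(rl$out, cfg$pool_size)
    a <- mp$out
  }
  d <- dim(a)
  tibble::tibble(
    channel = rep(seq_len(d[3]), each = d[2]),
    position = rep(seq_len(d[2]), times = d[3]),
    activation = as.vector(a[1, , ]))
}
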