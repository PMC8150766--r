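#' Fuse the classical and automatic embeddings
#'
#' End-to-end concatenation, classical half first: a 256-dimensional fusion
#' feature per segment.
#'
#' @param classical matrix `N x 128` (or vector of length 128).
#' @param automatic matrix `N x 128` (or vector).
#' @return Matrix `N x 256`.
#' @export
fuse <- function(classical, automatic) {
  if (is.vector(classical)) classical <- matrix(classical, 1)
  if (is.vector(automatic)) automatic <- matrix(automatic, 1)
  if (!all(is.finite(classical)) || !all(is.finite(automatic))) {
    abort("embeddings must be finite")
  }
  if (ncol(classical) != 128 || ncol(automatic) != 128 ||
      nrow(classical) != nrow(automatic)) {
    abort("expected two N x 128 embedding matrices")
  }
  cbind(classical, automatic)
}

#' Fusion-head configuration
#'
#' @param hidden hidden width of the fusion MLP (256 -> hidden -> 1).
#' @param dropout dropout rate before the output unit.
#' @param batch_size,epochs,lr,seed training knobs.
#' @return A `fusion_config` list.
#' @export
fusion_config <- function(hidden = 64, dropout = 0.3, batch_size = 32,
                          epochs = 100, lr = 1e-3, seed = 1L) {
  structure(as.list(environment()), class = "fusion_config")
}

fusion_head_forward <- function(params, x, cfg, training = FALSE) {
  f1 <- dense_forward(params$fc1, x)
  r1 <- relu_forward(f1$out)
  d1 <- dropout_forward(r1$out, cfg$dropout, training)
  f2 <- dense_forward(params$fc2, d1$out)
  p <- sigmoid(f2$out)
  list(p = as.numeric(p), caches = list(f1 = f1, r1 = r1, d1 = d1, f2 = f2, p = p))
}

fusion_head_backward <- function(params, fwd, y) {
  ca <- fwd$caches
  dp <- matrix(bce_grad(y, as.numeric(ca$p)), ncol = 1)
  dz2 <- dp * ca$p * (1 - ca$p)
  b2 <- dense_backward(params$fc2, ca$f2, dz2)
  dd1 <- dropout_backward(ca$d1, b2$dx)
  dr1 <- relu_backward(ca$r1, dd1)
  b1 <- dense_backward(params$fc1, ca$f1, dr1)
  list(fc1 = b1$grads, fc2 = b2$grads)
}

#' Train the fusion classifier on frozen branch embeddings
#'
#' Extracts the 128-d classical and automatic embeddings with the branch
#' weights frozen, concatenates them to the 256-d fusion feature, and trains
#' the MLP head (256 -> hidden -> 1 sigmoid) under binary cross-entropy.
#' Embeddings are standardized with training-set statistics.
#'
#' @param classical a trained `classical_branch`.
#' @param cnn a trained `cnn_branch`.
#' @param seq_train,seq_val feature-sequence arrays `N x T x 70`.
#' @param sig_train,sig_val raw-signal matrices `N x L`.
#' @param y_train,y_val labels in `{0, 1}`.
#' @param cfg a [fusion_config()].
#' @return A `fusion_model` holding both frozen branches, the head, scaler
#'   and history.
#' @export
train_fusion <- function(classical, cnn, seq_train, sig_train, y_train,
                         seq_val, sig_val, y_val, cfg = fusion_config()) {
  if (!inherits(classical, "classical_branch") || !inherits(cnn, "cnn_branch")) {
    abort("both branches must be trained before fusion")
  }
  emb_tr <- fuse(classical_predict(classical, seq_train)$embedding,
                 cnn_predict(cnn, sig_train)$embedding)
  emb_va <- fuse(classical_predict(classical, seq_val)$embedding,
                 cnn_predict(cnn, sig_val)$embedding)
  with_seed(cfg$seed, {
    sc <- standardizer_fit(emb_tr)
    xt <- sweep(sweep(emb_tr, 2, sc$mu), 2, sc$sd, `/`)
    xv <- sweep(sweep(emb_va, 2, sc$mu), 2, sc$sd, `/`)
    params <- list(fc1 = dense_init(256, cfg$hidden), fc2 = dense_init(cfg$hidden, 1))
    opt <- adam_init(params)
    best <- list(acc = -1, params = params)
    hist <- vector("list", cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      losses <- c()
      for (bi in make_batches(nrow(xt), cfg$batch_size)) {
        fwd <- fusion_head_forward(params, xt[bi, , drop = FALSE], cfg, training = TRUE)
        losses <- c(losses, bce_loss(y_train[bi], fwd$p))
        grads <- fusion_head_backward(params, fwd, y_train[bi])
        st <- adam_step(params, grads, opt, lr = cfg$lr)
        params <- st$params; opt <- st$state
      }
      vf <- fusion_head_forward(params, xv, cfg, training = FALSE)
      val_acc <- prob_accuracy(y_val, vf$p)
      if (val_acc > best$acc) best <- list(acc = val_acc, params = params)
      hist[[ep]] <- tibble::tibble(epoch = ep, train_loss = mean(losses),
                                   val_loss = bce_loss(y_val, vf$p),
                                   val_acc = val_acc)
    }
    structure(list(classical = classical, cnn = cnn, head = best$params,
                   scaler = sc, config = cfg, history = bind_rows(hist),
                   val_acc = best$acc,
                   fingerprint = config_fingerprint(cfg)),
              class = "fusion_model")
  })
}

#' Predict with the fused pipeline
#'
#' Deterministic inference: feature-sequence and raw-signal inputs go
#' through their frozen branches, the fused 256-d feature through the MLP
#' head. Label rule: ES if probability >= 0.5 (ties favour sensitivity).
#'
#' @param pipeline a `fusion_model`.
#' @param seq_x array `N x T x 70`.
#' @param sig_x matrix `N x L`.
#' @return Tibble with `segment_id`, `probability`, `label`, plus the fused
#'   features as an attribute `"fusion_features"` (`N x 256`).
#' @export
predict_fusion <- function(pipeline, seq_x, sig_x) {
  stopifnot(inherits(pipeline, "fusion_model"))
  emb <- fuse(classical_predict(pipeline$classical, seq_x)$embedding,
              cnn_predict(pipeline$cnn, sig_x)$embedding)
  xs <- sweep(sweep(emb, 2, pipeline$scaler$mu), 2, pipeline$scaler$sd, `/`)
  p <- fusion_head_forward(pipeline$head, xs, pipeline$config, training = FALSE)$p
  out <- tibble::tibble(segment_id = seq_len(nrow(emb)), probability = p,
                        label = ifelse(p >= 0.5, "ES", "NES"))
  attr(out, "fusion_features") <- emb
  out
}

#' Save / load a trained model with its config fingerprint
#'
#' @param model any branch or fusion model from this package.
#' @param path file path (RDS serialization).
#' @return `save_model()`: `path` invisibly. `load_model()`: the model; a
#'   fingerprint mismatch against the stored config aborts.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!is.null(model$fingerprint) &&
      !identical(model$fingerprint, config_fingerprint(model$config))) {
    abort("checkpoint fingerprint does not match its stored config")
  }
  model
}
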