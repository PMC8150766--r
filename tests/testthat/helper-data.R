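# Shared synthetic study dataset, built once per test run and cached so the
# end-to-end, separability and reproducibility tests reuse the same inputs.
# Conditions: 8 s segments at 512 Hz (4 x 2 s timesteps), default generator
# contrast, preprocessed to the common 160 Hz analysis path.

.fixture_cache <- new.env(parent = emptyenv())

study_dataset <- function(n_per_class = 400, seed = 42) {
  key <- sprintf("ds_%d_%d", n_per_class, seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  n <- 2 * n_per_class
  labels <- rep(c("ES", "NES"), each = n_per_class)
  y <- as.integer(labels == "ES")
  cfgp <- preprocess_config(window_seconds = 8, n_timesteps = 4)
  seq_arr <- array(0, dim = c(n, 4, 70))
  sig <- matrix(0, n, 8 * cfgp$analysis_fs)
  for (i in seq_len(n)) {
    seg <- generate_segment(synth_config(duration = 8, class_label = labels[i],
                                         seed = seed * 1000L + i))
    seq_arr[i, , ] <- extract_feature_sequence(seg, cfgp, n = 4)
    pre <- resample_segment(bandpass(seg, 0.5, 80), cfgp$analysis_fs)
    sig[i, ] <- pre$samples[1, ]
  }
  out <- list(seq = seq_arr, sig = sig, y = y, labels = labels,
              feature_names = feature_manifest()$name)
  .fixture_cache[[key]] <- out
  out
}

# stratified 80/20 train/validation indices for the cached dataset
study_split <- function(n_per_class = 400) {
  n_tr <- round(0.8 * n_per_class)
  list(train = c(seq_len(n_tr), n_per_class + seq_len(n_tr)),
       val = c((n_tr + 1):n_per_class, n_per_class + (n_tr + 1):n_per_class))
}

trained_branches <- function() {
  if (!is.null(.fixture_cache$models)) return(.fixture_cache$models)
  ds <- study_dataset()
  sp <- study_split()
  cl <- train_classical(ds$seq[sp$train, , ], ds$y[sp$train],
                        ds$seq[sp$val, , ], ds$y[sp$val],
                        classical_branch_config(epochs = 30, seed = 0))
  cn <- train_cnn(ds$sig[sp$train, ], ds$y[sp$train],
                  ds$sig[sp$val, ], ds$y[sp$val],
                  cnn_config(epochs = 20, seed = 0))
  fu <- train_fusion(cl, cn, ds$seq[sp$train, , ], ds$sig[sp$train, ],
                     ds$y[sp$train], ds$seq[sp$val, , ], ds$sig[sp$val, ],
                     ds$y[sp$val], fusion_config(epochs = 60, seed = 0))
  .fixture_cache$models <- list(classical = cl, cnn = cn, fusion = fu)
  .fixture_cache$models
}
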