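test_that("time-domain block follows the printed formulas", {
  td <- time_domain_features(c(1, 2, 3))
  expect_equal(td[["mean"]], 2)
  expect_equal(td[["variance"]], 2 / 3)      # population (1/N) variance

  expect_equal(time_domain_features(c(1, -1, 1, -1))[["zero_crossings"]], 3)

  x <- c(2, 4, 4, 4, 5, 5, 7, 9)
  td2 <- time_domain_features(x)
  expect_equal(td2[["hjorth_activity"]], td2[["variance"]])
  expect_equal(td2[["iqr"]],
               oracle_quantile_sorted_np1(x, 0.75) - oracle_quantile_sorted_np1(x, 0.25))

  # constant input: cv and ratios hit their 0 sentinels, nothing non-finite
  tdc <- time_domain_features(rep(5, 100))
  expect_true(all(is.finite(tdc)))
  expect_equal(tdc[["cv"]], 0)
})

test_that("moment features calibrate on Gaussian noise", {
  vals <- vapply(1:20, function(s) {
    set.seed(s)
    x <- rnorm(4096)
    td <- time_domain_features(x)
    c(td[["kurtosis"]], td[["hurst"]])
  }, numeric(2))
  expect_lt(abs(mean(vals[1, ])), 0.2)       # excess kurtosis near 0
  expect_lt(abs(mean(vals[2, ]) - 0.5), 0.1) # Hurst near 0.5
})

test_that("frequency-domain block behaves on known spectra", {
  fs <- 512
  tone100 <- sin(2 * pi * 100 * (0:4095) / fs)
  f <- frequency_domain_features(tone100, fs)
  expect_gt(f[["spr"]], 10)                          # tone inside 60-140 band
  expect_equal(f[["spectral_centroid"]], 100, tolerance = 1)

  tone20 <- sin(2 * pi * 20 * (0:4095) / fs)
  expect_lt(frequency_domain_features(tone20, fs)[["spr"]], 0.1)

  set.seed(50)
  w <- frequency_domain_features(rnorm(8192), fs)
  expect_gt(w[["spectral_entropy"]], 0.95)           # flat spectrum
  expect_lte(w[["spectral_entropy"]], 1)

  # Nyquist below the SPR numerator band: sentinel 0 with a warning
  expect_warning(low <- frequency_domain_features(rnorm(512), 100), "SPR")
  expect_equal(low[["spr"]], 0)
})

test_that("EMD produces near-complete decompositions and quartile features", {
  set.seed(51)
  x <- sin(2 * pi * 5 * (0:511) / 160) + 0.5 * rnorm(512)
  imfs <- emd(x, n_imfs = 5)
  expect_gte(length(imfs), 2)
  recon <- Reduce(`+`, imfs) + attr(imfs, "residual")
  expect_equal(recon, x, tolerance = 1e-9)           # sifting is subtractive

  ef <- emd_fuzzy_features(x)
  expect_length(ef, 2)
  expect_true(all(is.finite(ef)))
  expect_identical(ef, emd_fuzzy_features(x))        # deterministic

  fe <- vapply(imfs, function(im) fuzzy_entropy(im, 2, 0.2 * sd(im)), 0)
  expect_equal(ef[["emd_fuzzy_q1"]], oracle_quantile_sorted(fe, 0.25), tolerance = 1e-12)
  expect_equal(ef[["emd_fuzzy_q3"]], oracle_quantile_sorted(fe, 0.75), tolerance = 1e-12)
})

test_that("the full vector has 70 manifest-ordered finite entries", {
  man <- feature_manifest()
  expect_equal(nrow(man), 70)
  expect_equal(man$name[1], "mean")
  expect_equal(man$name[21], "kraskov_A4")
  expect_equal(man$name[70], "hfd_D1")
  expect_equal(as.vector(table(man$family)[c("time", "frequency", "tf", "nonlinear")]),
               c(12, 6, 2, 50))

  seg <- generate_segment(synth_config(duration = 4, class_label = "ES", seed = 52))
  fv <- extract_feature_vector(seg)
  expect_length(fv, 70)
  expect_identical(names(fv), man$name)
  expect_true(all(is.finite(fv)))
  expect_identical(fv, extract_feature_vector(seg))  # deterministic
})

test_that("scale-invariant entries ignore amplitude, energy scales quadratically", {
  seg <- generate_segment(synth_config(duration = 4, class_label = "NES", seed = 53))
  big <- seg
  big$samples <- seg$samples * 10
  f1 <- extract_feature_vector(seg)
  f2 <- extract_feature_vector(big)
  invariant <- c("cv", "spectral_entropy", "permutation_A4", "permutation_D1",
                 "hfd_A4", "hfd_D1", "pfd_D2", "svd_D3")
  for (nm in invariant) {
    expect_equal(f2[[nm]], f1[[nm]], tolerance = 1e-6, label = nm)
  }
  for (nm in paste0("energy_", c("A4", "D4", "D3", "D2", "D1"))) {
    expect_equal(f2[[nm]] / f1[[nm]], 100, tolerance = 1e-6)
  }
})

test_that("feature sequences carry n x 70 scalars and tidy output", {
  seg <- generate_segment(synth_config(duration = 8, seed = 54))
  m <- extract_feature_sequence(seg, preprocess_config(window_seconds = 8), n = 4)
  expect_equal(dim(m), c(4, 70))
  expect_equal(length(m), 280)

  m1 <- extract_feature_sequence(seg, preprocess_config(window_seconds = 8), n = 1)
  expect_equal(dim(m1), c(1, 70))

  tbl <- extract_feature_table(list(seg), n = 4)
  expect_s3_class(tbl, "tbl_df")
  expect_equal(nrow(tbl), 4)
  expect_true(all(feature_manifest()$name %in% names(tbl)))
})
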