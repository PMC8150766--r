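test_that("metrics follow their defining ratios", {
  m <- compute_metrics(list(tp = 50, tn = 40, fp = 10, fn = 0))
  expect_equal(m$se, 1.0)
  expect_equal(m$acc, 0.90)
  expect_equal(m$sp, 0.80)

  m2 <- compute_metrics(list(tp = 25, tn = 25, fp = 25, fn = 25))
  expect_equal(unlist(m2[c("acc", "se", "sp")], use.names = FALSE), rep(0.5, 3))

  expect_warning(m3 <- compute_metrics(list(tp = 0, tn = 5, fp = 5, fn = 0)),
                 "sensitivity")
  expect_true(is.na(m3$se))
})

test_that("accuracy decomposes by prevalence over random confusion tables", {
  set.seed(90)
  for (i in 1:100) {
    c_ <- as.list(stats::setNames(sample(1:50, 4, replace = TRUE),
                                  c("tp", "tn", "fp", "fn")))
    m <- compute_metrics(c_)
    pi_ <- (c_$tp + c_$fn) / (c_$tp + c_$tn + c_$fp + c_$fn)
    expect_equal(m$acc, pi_ * m$se + (1 - pi_) * m$sp, tolerance = 1e-12)
  }
})

test_that("confusion counts agree with a brute-force tally", {
  set.seed(91)
  truth <- sample(c("ES", "NES"), 1000, replace = TRUE)
  pred <- sample(c("ES", "NES"), 1000, replace = TRUE)
  cc <- confusion_counts(truth, pred)
  expect_equal(cc$tp, sum(truth == "ES" & pred == "ES"))
  expect_equal(cc$fn, sum(truth == "ES" & pred == "NES"))
  expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, 1000)
  m <- compute_metrics(cc)
  expect_equal(m$acc, mean(truth == pred), tolerance = 1e-12)
})

test_that("holdout and intra-subject splits are stratified, exact and reproducible", {
  ds <- tibble::tibble(segment_id = 1:1000,
                       label = rep(c("ES", "NES"), each = 500),
                       patient_id = rep(sprintf("P%d", 1:5), times = 200))
  sp <- make_split(ds, "random_holdout", c(0.7, 0.3), seed = 4)
  expect_equal(sum(sp$role == "train"), 700)
  expect_equal(sum(sp$role == "test"), 300)
  expect_identical(sp, make_split(ds, "random_holdout", c(0.7, 0.3), seed = 4))

  ds100 <- tibble::tibble(segment_id = 1:100,
                          label = rep(c("ES", "NES"), 50),
                          patient_id = "P1")
  sp3 <- make_split(ds100, "intra_subject", c(0.6, 0.1, 0.3), seed = 5)
  expect_equal(as.vector(table(sp3$role)[c("train", "val", "test")]),
               c(60, 10, 30))
  # stratification: each role holds both classes in equal shares
  joined <- dplyr::left_join(sp3, ds100, by = "segment_id")
  tab <- table(joined$role, joined$label)
  expect_true(all(tab[, "ES"] == tab[, "NES"]))

  expect_error(make_split(ds, "random_holdout", c(0.7, 0.4)), "sum to 1")
})

test_that("cross-subject folds never leak a patient into both sides", {
  ds <- tibble::tibble(segment_id = 1:500,
                       label = rep(c("ES", "NES"), 250),
                       patient_id = rep(sprintf("P%d", 1:5), each = 100))
  sp <- make_split(ds, "cross_subject", seed = 6)
  expect_equal(length(unique(sp$fold)), 5)   # one fold per held-out subject
  joined <- dplyr::left_join(sp, ds, by = "segment_id")
  for (k in unique(sp$fold)) {
    f <- joined[joined$fold == k, ]
    overlap <- intersect(f$patient_id[f$role == "train"],
                         f$patient_id[f$role == "test"])
    expect_length(overlap, 0)
    expect_length(unique(f$patient_id[f$role == "test"]), 1)
  }
  expect_error(make_split(ds[ds$patient_id == "P1", ], "cross_subject"),
               ">= 2 patients")
})

test_that("fold aggregation reproduces the published clinical averages", {
  intra <- tibble::tibble(acc = c(97.14, 87.35, 91.09, 91.96, 95.13))
  agg <- aggregate_folds(intra)
  expect_equal(round(agg$mean[agg$metric == "acc"], 2), 92.53)
  expect_equal(agg$min[agg$metric == "acc"], 87.35)
  expect_equal(agg$max[agg$metric == "acc"], 97.14)

  cross <- tibble::tibble(acc = c(87.59, 87.68, 90.30, 88.93, 85.63))
  expect_equal(round(aggregate_folds(cross)$mean, 2), 88.03)

  expect_warning(one <- aggregate_folds(tibble::tibble(acc = 90)), "single fold")
  expect_equal(one$sem, 0)
  expect_error(aggregate_folds(tibble::tibble(acc = numeric(0))), "no folds")
})

test_that("result tables format deterministically in percent style", {
  res <- tibble::tibble(method = c("fusion", "classical", "cnn"),
                        feature_set = "x",
                        acc = c(0.976, 0.972, 0.8987),
                        se = c(0.9778, 0.9729, 0.9013),
                        sp = c(0.9742, 0.971, 0.8959))
  out <- report_results(res)
  expect_equal(nrow(out), 3)
  expect_equal(out$method, sort(res$method))
  expect_equal(out$acc[out$method == "fusion"], "97.60%")
  expect_identical(out, report_results(res))
})
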