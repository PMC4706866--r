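test_that("chronological split respects order and the odd-count rule", {
  ep <- noise_epochs(n_trials = 320, n_channels = 2, span = c(0, 0.05),
                     labels = rep(c("C", "NC"), 160))
  halves <- chronological_split(ep)
  expect_equal(n_trials(halves$train), 160)
  expect_equal(n_trials(halves$test), 160)
  expect_identical(halves$train$labels, ep$labels[1:160])
  expect_identical(halves$test$labels, ep$labels[161:320])
  ep321 <- noise_epochs(n_trials = 321, n_channels = 2, span = c(0, 0.05),
                        labels = c(rep(c("C", "NC"), 160), "C"))
  h <- chronological_split(ep321)
  expect_equal(n_trials(h$train), 161)
  expect_equal(n_trials(h$test), 160)
  bad <- noise_epochs(n_trials = 8, n_channels = 2, span = c(0, 0.05),
                      labels = c(rep("C", 6), "NC", "NC"))
  expect_error(chronological_split(bad), "absent")
})

test_that("ERP feature counts follow the window/decimation arithmetic", {
  vc <- noise_epochs(n_trials = 10, n_channels = 5, seed = 31)
  f <- erp_features(vc)
  expect_equal(ncol(f$values), 160)   # 5 x 512 x 1 s / 16
  expect_equal(nrow(f$values), 10)
  f2 <- erp_features(vc, window_length = 0.5)
  expect_equal(ncol(f2$values), 80)
  const <- vc
  const$data[] <- 3.14
  fc <- erp_features(const)
  expect_true(all(fc$values == 3.14))
  expect_error(erp_features(vc, window_start = 2.0, window_length = 1.0),
               "window")
})

test_that("CSSP features: 24 per epoch, log-variance scaling, missing bank", {
  ep <- noise_epochs(n_trials = 20, n_channels = 28, seed = 33)
  cfg <- pipeline_config(feature_set = "ERP+CSSP")
  banks <- lapply(cfg$cssp_bands, function(b)
    fit_cssp(comfortEEG:::crop_epochs(butter_band(ep, b, 3), 1.1, 1.0),
             band = b, n_pairs = 3, delay = 1))
  f <- cssp_features(ep, banks)
  expect_equal(ncol(f$values), 24)    # 4 bands x 2*3 components
  ep2 <- ep
  ep2$data <- 2 * ep$data
  f2 <- cssp_features(ep2, banks)
  expect_equal(f2$values - f$values,
               matrix(log(4), nrow(f$values), 24), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(cssp_features(ep, c(banks[1:3], list(bad = NULL))),
               "missing or invalid")
})

test_that("fusion z-scores with training statistics only", {
  ep <- noise_epochs(n_trials = 24, n_channels = 28, seed = 35)
  halves <- chronological_split(ep)
  bank <- fit_refsf(comfortEEG:::crop_epochs(halves$train, 0.1, 1.0), 5)
  erp_tr <- erp_features(apply_filters(halves$train, bank))
  erp_te <- erp_features(apply_filters(halves$test, bank))
  cfg <- pipeline_config(feature_set = "ERP+CSSP")
  banks <- lapply(cfg$cssp_bands, function(b)
    fit_cssp(comfortEEG:::crop_epochs(butter_band(halves$train, b, 3),
                                      1.1, 1.0),
             band = b, n_pairs = 3, delay = 1))
  cs_tr <- cssp_features(halves$train, banks)
  cs_te <- cssp_features(halves$test, banks)
  fz <- fuse_and_normalize(list(erp_tr, cs_tr), list(erp_te, cs_te))
  expect_equal(ncol(fz$train$values), 184)   # 160 + 24
  expect_lt(max(abs(colMeans(fz$train$values))), 1e-10)
  expect_equal(apply(fz$train$values, 2, sd), rep(1, 184),
               tolerance = 1e-10, ignore_attr = TRUE)
  # test set keeps a deliberate shift: normalized with training parameters
  shifted <- cs_te
  shifted$values <- cs_te$values + 5
  fz2 <- fuse_and_normalize(list(erp_tr, cs_tr), list(erp_te, shifted))
  delta <- colMeans(fz2$test$values[, 161:184]) -
    colMeans(fz$test$values[, 161:184])
  expect_true(all(delta > 0))
  expect_error(fuse_and_normalize(erp_tr, cs_te), "provenance")
})

test_that("median-ratio selection keeps k features with sane ordering", {
  set.seed(37)
  n <- 60
  vals <- cbind(
    c(rnorm(n / 2, 10, 0.5), rnorm(n / 2, 0.5, 0.2)),  # disjoint supports
    rnorm(n, 5, 1),                                    # identical medians
    c(rnorm(n / 2, 2, 0.5), rnorm(n / 2, 4, 0.5)))
  fm <- feature_matrix(vals, rep(c("C", "NC"), each = n / 2),
                       paste0("f", 1:3))
  mask <- median_ratio_select(fm, k = 2)
  expect_length(mask$indices, 2)
  expect_true(1 %in% mask$indices)
  expect_false(2 %in% mask$indices)
  expect_gt(mask$scores[1], mask$scores[3])
  ident <- median_ratio_select(fm, k = 3)
  expect_equal(ident$indices, 1:3)
  expect_error(median_ratio_select(fm, k = 10), "k exceeds")
  big <- feature_matrix(matrix(rnorm(40 * 184), 40),
                        rep(c("C", "NC"), 20), paste0("f", 1:184))
  expect_length(median_ratio_select(big, 50)$indices, 50)
})

test_that("shrinkage LDA spans classical LDA and nearest-mean limits", {
  set.seed(41)
  n <- 100
  d <- 6
  X <- rbind(matrix(rnorm(n * d), n), sweep(matrix(rnorm(n * d), n), 2,
                                            c(2, 1, 0, 0, -1, 0), `+`))
  labels <- rep(c("NC", "C"), each = n)
  m0 <- fit_slda(X, labels, shrinkage = 0)
  ld <- MASS::lda(X, grouping = labels)
  # MASS order is alphabetical (C, NC); its LD1 is an independent oracle
  expect_gt(abs_cosine(m0$weights, ld$scaling[, 1]), 0.999)
  m1 <- fit_slda(X, labels, shrinkage = 1)
  mu_diff <- colMeans(X[labels == "C", ]) - colMeans(X[labels == "NC", ])
  expect_gt(abs_cosine(m1$weights, mu_diff), 0.999)
  # far-separated blobs classify their own training data perfectly
  Xfar <- rbind(matrix(rnorm(40 * 3), 40), matrix(rnorm(40 * 3) + 50, 40))
  lab <- rep(c("C", "NC"), each = 40)
  mf <- fit_slda(Xfar, lab)
  expect_equal(mean(predict_slda(mf, Xfar)$labels == lab), 1)
  expect_error(fit_slda(X, labels, shrinkage = 2), "shrinkage")
  expect_error(fit_slda(X[1:3, ], labels[c(1, 2, 101)]), "2 trials")
})

test_that("prediction scores are signed, tie-broken to C, symmetric", {
  set.seed(43)
  X <- rbind(matrix(rnorm(60, 2), 20, 3), matrix(rnorm(60, -2), 20, 3))
  labels <- rep(c("C", "NC"), each = 20)
  m <- fit_slda(X, labels, shrinkage = 0.1)
  mid <- (m$class_means[1, ] + m$class_means[2, ]) / 2
  p_mid <- predict_slda(m, matrix(mid, 1))
  expect_equal(p_mid$scores, 0, tolerance = 1e-10)
  expect_equal(p_mid$labels, "C")
  p_means <- predict_slda(m, m$class_means)
  expect_identical(p_means$labels, c("C", "NC"))
  # flipping which class is which flips score signs, not accuracy
  m_flip <- fit_slda(X, ifelse(labels == "C", "NC", "C"), shrinkage = 0.1)
  p <- predict_slda(m, X)
  pf <- predict_slda(m_flip, X)
  expect_gt(stats::cor(p$scores, -pf$scores), 0.999)
  expect_equal(mean(p$labels == labels),
               mean(pf$labels == ifelse(labels == "C", "NC", "C")))
  expect_error(predict_slda(m, matrix(0, 2, 5)), "feature count")
})

test_that("pipeline fits everything on the training half only", {
  ep <- toy_epochs(n_per_class = 30, n_channels = 6,
                   pattern = c(0, 1, 0, 0, 0.5, 0), seed = 47,
                   noise_sd = 2)
  # interleave labels chronologically so the split holds both classes
  ord <- as.vector(rbind(1:30, 31:60))
  ep <- comfortEEG:::subset_trials(ep, ord)
  cfg <- pipeline_config(erp_window_start = 0, erp_window_length = 0.1,
                         decimation = 4, n_refsf_components = 2,
                         epoch_span = c(0, 0.125))
  r1 <- comfortEEG:::run_subject_epochs(ep, cfg)
  # permute the test-half labels: the fitted model must not change
  ep_perm <- ep
  set.seed(1)
  idx_test <- 31:60
  ep_perm$labels[idx_test] <- sample(ep_perm$labels[idx_test])
  r2 <- comfortEEG:::run_subject_epochs(ep_perm, cfg)
  expect_identical(r1$model$weights, r2$model$weights)
  expect_identical(r1$bank$weights, r2$bank$weights)
  expect_identical(r1$predictions, r2$predictions)
  expect_false(isTRUE(all.equal(r1$accuracy, r2$accuracy)))
})

test_that("shuffled training labels give chance-level test accuracy", {
  accs <- vapply(1:20, function(rep) {
    ep <- toy_epochs(n_per_class = 24, n_channels = 4,
                     pattern = c(0, 1, 0, 0), seed = 100 + rep,
                     noise_sd = 1.5)
    ord <- as.vector(rbind(1:24, 25:48))
    ep <- comfortEEG:::subset_trials(ep, ord)
    set.seed(rep)
    ep$labels[1:24] <- sample(ep$labels[1:24])  # destroy training signal
    cfg <- pipeline_config(erp_window_start = 0, erp_window_length = 0.1,
                           decimation = 4, n_refsf_components = 2,
                           epoch_span = c(0, 0.125))
    comfortEEG:::run_subject_epochs(ep, cfg)$accuracy
  }, numeric(1))
  ci <- mean(accs) + c(-1, 1) * qt(0.975, 19) * sd(accs) / sqrt(20)
  expect_lt(ci[1], 50)
  expect_gt(ci[2], 50)
})

test_that("run_subject is deterministic and its config snapshot is kept", {
  cfg <- small_config(n_trials_per_condition = 16L)
  s <- generate_session(cfg, "S01", seed = 55)
  pc <- pipeline_config(mode = "online")
  r1 <- run_subject(s, pc)
  r2 <- run_subject(s, pc)
  expect_identical(r1$predictions, r2$predictions)
  expect_equal(r1$accuracy, r2$accuracy)
  expect_equal(r1$n_test, 16)
  expect_identical(r1$config$mode, "online")
  expect_null(r1$rejection)
})

test_that("offline and online modes differ only by the rejection stage", {
  cfg <- small_config(n_trials_per_condition = 16L)
  s <- generate_session(cfg, "S01", seed = 57)
  off <- run_subject(s, pipeline_config(mode = "offline"))
  on <- run_subject(s, pipeline_config(mode = "online"))
  # clean synthetic data rejects nothing, so results coincide exactly
  expect_length(off$rejection$rejected_indices, 0)
  expect_identical(off$predictions, on$predictions)
  expect_equal(off$accuracy, on$accuracy)
})

test_that("accuracy grows with the ERP effect size", {
  chans <- default_channels()[seq(1, 28, by = 2)]
  accs <- vapply(c(0, 2, 4.5, 7), function(gain) {
    cfg <- make_default_config(n_trials_per_condition = 80L,
                               eeg_channels = chans,
                               erp_peak_gain_C = gain,
                               inter_subject_sd = 0)
    s <- generate_session(cfg, "S01", seed = 301)
    run_subject(s, pipeline_config())$accuracy
  }, numeric(1))
  # non-decreasing over the gain grid, within simulation noise
  expect_true(all(diff(accs) > -8))
  expect_gt(accs[4], accs[1] + 10)
  expect_lt(abs(accs[1] - 50), 15)   # null effect is near chance
})
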