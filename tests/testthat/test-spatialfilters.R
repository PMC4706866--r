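test_that("top REFSF filter matches a brute-force Fisher maximizer", {
  ep <- toy_epochs(n_per_class = 60, n_channels = 2, pattern = c(0.8, -0.6),
                   kernel_amp = 1.5, seed = 11)
  sc <- comfortEEG:::refsf_scatter(ep)
  lam <- 0.05
  Sw <- (1 - lam) * sc$S_w + lam * diag(mean(diag(sc$S_w)), 2)
  oracle <- grid_fisher_filter(sc$S_b, Sw)
  bank <- fit_refsf(ep, n_components = 1, shrink = lam)
  expect_gt(abs_cosine(bank$weights[, 1], oracle), 0.99)
})

test_that("REFSF localizes a single-channel effect and respects symmetry", {
  ep <- toy_epochs(n_per_class = 50, n_channels = 4,
                   pattern = c(0, 0, 1, 0), kernel_amp = 2, seed = 3)
  bank <- fit_refsf(ep, n_components = 2)
  expect_equal(which.max(abs(bank$weights[, 1])), 3L)
  expect_equal(dim(bank$weights), c(4L, 2L))
  expect_true(all(diff(bank$eigenvalues) <= 1e-10))
  # permuting channels permutes the weight rows identically (up to sign)
  perm <- c(2, 4, 1, 3)
  ep_p <- ep
  ep_p$data <- ep$data[, perm, , drop = FALSE]
  ep_p$channel_labels <- ep$channel_labels[perm]
  bank_p <- fit_refsf(ep_p, n_components = 2, shrink = bank$shrinkage)
  expect_gt(abs_cosine(bank_p$weights[, 1], bank$weights[perm, 1]), 0.999)
  # scale invariance of the filter direction
  ep_s <- ep
  ep_s$data <- ep$data * 7
  bank_s <- fit_refsf(ep_s, n_components = 2, shrink = bank$shrinkage)
  expect_gt(abs_cosine(bank_s$weights[, 1], bank$weights[, 1]), 0.999)
})

test_that("REFSF components are S_w-orthogonal with decreasing Fisher ratio", {
  ep <- toy_epochs(n_per_class = 60, n_channels = 4,
                   pattern = c(0, 0, 1, 0.3), kernel_amp = 2, seed = 13)
  # second weaker effect on another channel, different time course
  kern2 <- 1 * cos(pi * seq_len(dim(ep$data)[3]) / dim(ep$data)[3])
  for (i in 1:60)
    ep$data[i, 2, ] <- ep$data[i, 2, ] + kern2
  bank <- fit_refsf(ep, n_components = 3, shrink = 0.05)
  sc <- comfortEEG:::refsf_scatter(ep)
  Sw <- (1 - bank$shrinkage) * sc$S_w +
    bank$shrinkage * diag(mean(diag(sc$S_w)), 4)
  G <- t(bank$weights) %*% Sw %*% bank$weights
  off <- G - diag(diag(G))
  expect_lt(max(abs(off)), 1e-8 * max(diag(G)))
  # empirical Fisher ratio of projections is non-increasing
  ratios <- vapply(1:3, function(k) {
    w <- bank$weights[, k]
    (w %*% sc$S_b %*% w) / (w %*% sc$S_w %*% w)
  }, numeric(1))
  expect_true(all(diff(ratios) <= 1e-8))
})

test_that("filter projection is linear with virtual-channel labels", {
  ep <- noise_epochs(n_trials = 6, n_channels = 4, seed = 8)
  ident <- structure(
    list(weights = diag(4), eigenvalues = rep(1, 4), method = "REFSF",
         band = NULL, delay = NULL, channel_labels = ep$channel_labels),
    class = "spatial_filter_bank")
  out <- apply_filters(ep, ident)
  expect_equal(out$data, ep$data, ignore_attr = TRUE)
  expect_identical(out$channel_labels, paste0("VC", 1:4))
  ep2 <- ep
  ep2$data <- 3 * ep$data
  expect_equal(apply_filters(ep2, ident)$data, 3 * out$data,
               ignore_attr = TRUE)
  bad <- ident
  bad$channel_labels <- rev(bad$channel_labels)
  expect_error(apply_filters(ep, bad), "labels")
})

test_that("band filters pass in-band and reject out-of-band content", {
  fs <- 512
  t <- (0:(6 * fs - 1)) / fs
  n_samp <- length(t)
  data <- array(0, dim = c(2, 2, n_samp))
  data[1, 1, ] <- sin(2 * pi * 10 * t)   # in alpha band
  data[2, 1, ] <- sin(2 * pi * 10 * t)
  data[1, 2, ] <- sin(2 * pi * 2 * t)    # below alpha band
  data[2, 2, ] <- sin(2 * pi * 2 * t)
  ep <- epoch_set(data, c("C", "NC"), times = t, sampling_rate = fs,
                  channel_labels = c("a", "b"))
  out <- butter_band(ep, c(7, 13), order = 3)
  expect_identical(dim(out$data), dim(ep$data))
  mid <- 1000:2000
  g_in <- stats::sd(out$data[1, 1, mid]) / stats::sd(data[1, 1, mid])
  g_out <- stats::sd(out$data[1, 2, mid]) / stats::sd(data[1, 2, mid])
  expect_gt(g_in, 0.9)
  expect_lt(g_in, 1.1)
  expect_lt(g_out, 0.1)
  expect_error(butter_band(ep, c(13, 7)), "increasing")
})

test_that("CSSP with zero delay reduces to CSP and matches a grid oracle", {
  # class C has extra variance along a fixed spatial direction
  set.seed(17)
  n_per <- 60
  n_samp <- 128
  dir_c <- c(0.9, 0.45)
  data <- array(rnorm(2 * n_per * 2 * n_samp), dim = c(2 * n_per, 2, n_samp))
  for (i in seq_len(n_per))
    data[i, , ] <- data[i, , ] + dir_c %o% rnorm(n_samp, sd = 1.5)
  ep <- epoch_set(data, rep(c("C", "NC"), each = n_per),
                  times = (0:(n_samp - 1)) / 512, sampling_rate = 512,
                  channel_labels = c("x", "y"))
  bank <- fit_cssp(ep, band = c(7, 13), n_pairs = 1, delay = 0)
  C1 <- class_cov(ep, "C")
  C2 <- class_cov(ep, "NC")
  oracle <- grid_csp_filter(C1, C2)
  expect_gt(abs_cosine(bank$weights[, 1], oracle), 0.99)
  # whitening normalization: w' (C1 + C2) w = 1 for every filter
  q <- diag(t(bank$weights) %*% (C1 + C2) %*% bank$weights)
  expect_equal(unname(q), rep(1, 2), tolerance = 1e-8)
  # eigenvalues of the two class problems pair to 1
  bank_sw <- fit_cssp(local({
    e <- ep
    e$labels <- ifelse(e$labels == "C", "NC", "C")
    e
  }), band = c(7, 13), n_pairs = 1, delay = 0)
  expect_equal(sort(bank$eigenvalues) + rev(sort(bank_sw$eigenvalues)),
               rep(1, 2), tolerance = 1e-8)
})

test_that("delay embedding doubles the filter rows and keeps the contract", {
  ep <- noise_epochs(n_trials = 40, n_channels = 6, seed = 19,
                     span = c(0, 0.5))
  bank <- fit_cssp(ep, band = c(7, 13), n_pairs = 2, delay = 1)
  expect_equal(nrow(bank$weights), 12)
  expect_equal(ncol(bank$weights), 4)
  expect_equal(bank$delay, 1L)
  expect_error(fit_cssp(ep, n_pairs = 10, delay = 0), "n_pairs")
})

test_that("channel importance maps per-subject extremes to [-1, 1]", {
  ep <- toy_epochs(n_per_class = 40, n_channels = 4,
                   pattern = c(0, 1, 0, 0.2), seed = 23)
  bank <- fit_refsf(ep, n_components = 2)
  ci <- channel_importance(list(bank), top_k = 2)
  expect_equal(min(ci$table$score), -1)
  expect_equal(max(ci$table$score), 1)
  expect_setequal(ci$table$rank, 1:4)
  expect_length(ci$selected, 2)
  # identical banks across subjects leave the cohort score unchanged
  ci3 <- channel_importance(list(bank, bank, bank), top_k = 2)
  expect_equal(ci3$table$score, ci$table$score)
  expect_identical(ci3$selected, ci$selected)
  # degenerate all-equal weights map to 0 with a warning
  flat <- bank
  flat$weights <- matrix(1, 4, 2)
  expect_warning(ci_f <- channel_importance(list(flat), top_k = 2),
                 "degenerate")
  expect_equal(ci_f$table$score, rep(0, 4))
})
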