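# Shared fixtures and independent oracles for the test suite.

# A scaled-down generative configuration for module tests: full channel
# montage and sampling rate, fewer trials so sessions stay small.
small_config <- function(...) {
  make_default_config(n_subjects = 2L, n_trials_per_condition = 12L,
                      inter_subject_sd = 0, ...)
}

# Epoch set built directly from seeded white noise: trials x channels x
# samples, 512 Hz, span [-1, 2.5) like the real pipeline sees.
noise_epochs <- function(n_trials = 16, n_channels = 28, seed = 42,
                         fs = 512, span = c(-1, 2.5), sd_uv = 10,
                         labels = NULL) {
  set.seed(seed)
  n_samp <- round((span[2] - span[1]) * fs)
  if (is.null(labels))
    labels <- rep(c("C", "NC"), length.out = n_trials)
  chans <- if (n_channels == 28) default_channels() else
    paste0("ch", seq_len(n_channels))
  epoch_set(array(rnorm(n_trials * n_channels * n_samp, sd = sd_uv),
                  dim = c(n_trials, n_channels, n_samp)),
            labels = labels,
            times = (round(span[1] * fs) + 0:(n_samp - 1)) / fs,
            sampling_rate = fs, channel_labels = chans)
}

# Two-class toy epochs on few channels: class "C" carries an extra additive
# spatial pattern `pattern` modulated by a smooth temporal kernel.
toy_epochs <- function(n_per_class = 40, n_channels = 2, n_samp = 64,
                       pattern = c(1, 0), kernel_amp = 2, seed = 7,
                       noise_sd = 1) {
  set.seed(seed)
  labels <- rep(c("C", "NC"), each = n_per_class)
  data <- array(rnorm(2 * n_per_class * n_channels * n_samp, sd = noise_sd),
                dim = c(2 * n_per_class, n_channels, n_samp))
  kern <- kernel_amp * sin(pi * seq_len(n_samp) / n_samp)
  for (i in seq_len(n_per_class))
    data[i, , ] <- data[i, , ] + pattern %o% kern
  epoch_set(data, labels, times = (0:(n_samp - 1)) / 512,
            sampling_rate = 512,
            channel_labels = paste0("ch", seq_len(n_channels)))
}

# Brute-force Fisher-criterion maximizer over unit vectors on 2 channels:
# dense scan of the angle, independent of the eigen solver.
grid_fisher_filter <- function(S_b, S_w, n_grid = 4000) {
  stopifnot(nrow(S_b) == 2)
  theta <- seq(0, pi, length.out = n_grid)
  best <- -Inf
  best_w <- c(1, 0)
  for (th in theta) {
    w <- c(cos(th), sin(th))
    r <- (w %*% S_b %*% w) / (w %*% S_w %*% w)
    if (r > best) {
      best <- r
      best_w <- w
    }
  }
  best_w
}

# Brute-force CSP maximizer on 2 channels: maximize w'C1w / w'(C1+C2)w.
grid_csp_filter <- function(C1, C2, n_grid = 4000) {
  grid_fisher_filter(C1, C1 + C2, n_grid)
}

# Trace-normalized average spatial covariance of one class, the oracle
# route for CSP checks (no delay embedding).
class_cov <- function(epochs, class) {
  idx <- which(epochs$labels == class)
  acc <- 0
  for (i in idx) {
    X <- epochs$data[i, , ]
    C <- tcrossprod(X)
    acc <- acc + C / sum(diag(C))
  }
  acc / length(idx)
}

abs_cosine <- function(a, b) {
  abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
}
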