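#' Trials-by-features matrix with provenance
#'
#' @param values numeric matrix, trials x features.
#' @param labels per-trial condition labels.
#' @param provenance character vector, one tag per feature.
#' @return A `feature_matrix`.
#' @export
feature_matrix <- function(values, labels, provenance) {
  values <- as.matrix(values)
  if (nrow(values) != length(labels))
    stop("label count does not match trial count")
  if (ncol(values) != length(provenance))
    stop("provenance length does not match feature count")
  structure(list(values = values, labels = as.character(labels),
                 provenance = as.character(provenance)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d trials x %d features\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Chronological train/test split
#'
#' Splits by recording order: the first half of the trials trains, the
#' second half tests; with an odd count the extra trial goes to training.
#'
#' @param epochs an [epoch_set()] in recording order.
#' @return List with `train` and `test` [epoch_set()]s.
#' @export
chronological_split <- function(epochs) {
  n <- n_trials(epochs)
  if (n < 4) stop("need at least 4 trials to split")
  n_train <- ceiling(n / 2)
  train <- subset_trials(epochs, seq_len(n_train))
  test <- subset_trials(epochs, (n_train + 1):n)
  for (half in list(train, test))
    if (length(unique(half$labels)) < length(unique(epochs$labels)))
      stop("a class is absent from one half of the chronological split")
  list(train = train, test = test)
}

#' Decimated ERP amplitude features from virtual channels
#'
#' Crops each virtual-channel epoch to the feature window, keeps every
#' `decimation`-th sample and concatenates the channels. With 5 virtual
#' channels, a 1 s window at 512 Hz and decimation 16 this yields
#' 5 x 512 / 16 = 160 features per epoch. Plain subsampling is used: the
#' preceding 25 Hz low-pass already bounds the spectral content relative to
#' the post-decimation Nyquist frequency (16 Hz).
#'
#' @param virtual an [epoch_set()] of spatially filtered epochs.
#' @param window_start window start in seconds (default 0.100, absorbing the
#'   fixed display latency).
#' @param window_length window length in seconds (default 1.0).
#' @param decimation subsampling factor (default 16).
#' @return A [feature_matrix()] with provenance tags `ERP:<channel>:<k>`.
#' @export
erp_features <- function(virtual, window_start = 0.100, window_length = 1.0,
                         decimation = 16) {
  if (window_start < virtual$times[1] - 1e-9 ||
      window_start + window_length > max(virtual$times) + 1 /
        virtual$sampling_rate + 1e-9)
    stop("feature window exceeds the epoch span")
  cropped <- crop_epochs(virtual, window_start, window_length)
  keep <- seq(1, dim(cropped$data)[3], by = decimation)
  d <- dim(cropped$data)
  vals <- matrix(0, d[1], d[2] * length(keep))
  prov <- character(d[2] * length(keep))
  for (ch in seq_len(d[2])) {
    cols <- (ch - 1) * length(keep) + seq_along(keep)
    vals[, cols] <- cropped$data[, ch, keep]
    prov[cols] <- sprintf("ERP:%s:%d", cropped$channel_labels[ch],
                          seq_along(keep))
  }
  feature_matrix(vals, cropped$labels, prov)
}

#' Log band-power features from CSSP filter banks
#'
#' For each band bank: band-pass the epochs (order-3 Butterworth), crop to
#' the spectral feature window, delay-embed, project through the bank and
#' take the log variance of each projected component; bands are
#' concatenated. The default window starts 1 s after the corrected stimulus
#' appearance (1000 ms + 100 ms display latency), where the condition
#' band-power modulation is expressed.
#'
#' @param epochs an [epoch_set()] of (unfiltered) channel epochs.
#' @param banks named list of CSSP `spatial_filter_bank`s, one per band.
#' @param window_start window start in seconds (default 1.100).
#' @param window_length window length in seconds (default 1.0).
#' @param order Butterworth order for the band filters.
#' @return A [feature_matrix()] with provenance tags `CSSP:<lo>-<hi>:<k>`.
#' @export
cssp_features <- function(epochs, banks, window_start = 1.100,
                          window_length = 1.0, order = 3) {
  if (length(banks) == 0) stop("no CSSP banks given")
  parts <- lapply(banks, function(bank) {
    if (is.null(bank) || !inherits(bank, "spatial_filter_bank") ||
        bank$method != "CSSP" || is.null(bank$band))
      stop("missing or invalid CSSP band bank")
    filt <- butter_band(epochs, bank$band, order)
    cropped <- crop_epochs(filt, window_start, window_length)
    k <- ncol(bank$weights)
    vals <- matrix(0, n_trials(cropped), k)
    for (i in seq_len(n_trials(cropped))) {
      Y <- crossprod(bank$weights, delay_augment(cropped$data[i, , ],
                                                 bank$delay))
      vals[i, ] <- log(apply(Y, 1, stats::var))
    }
    list(vals = vals,
         prov = sprintf("CSSP:%g-%g:%d", bank$band[1], bank$band[2],
                        seq_len(k)))
  })
  feature_matrix(do.call(cbind, lapply(parts, `[[`, "vals")),
                 epochs$labels,
                 unlist(lapply(parts, `[[`, "prov")))
}

#' Concatenate feature sets and z-score with training statistics
#'
#' Feature matrices (e.g. ERP and CSSP blocks) are concatenated along the
#' feature axis; per-feature mean and standard deviation are estimated on
#' the training set only and applied to both sets. Zero-variance training
#' features are dropped (and recorded in the returned parameters).
#'
#' @param train_feats a [feature_matrix()] or list of them (training set).
#' @param test_feats matching [feature_matrix()] or list (test set).
#' @return List with `train`, `test` (normalized [feature_matrix()]s) and
#'   `params` (`mean`, `sd`, `dropped` provenance tags).
#' @export
fuse_and_normalize <- function(train_feats, test_feats) {
  cat_fm <- function(x) {
    if (inherits(x, "feature_matrix")) return(x)
    feature_matrix(do.call(cbind, lapply(x, `[[`, "values")),
                   x[[1]]$labels,
                   unlist(lapply(x, `[[`, "provenance")))
  }
  tr <- cat_fm(train_feats)
  te <- cat_fm(test_feats)
  if (!identical(tr$provenance, te$provenance))
    stop("train and test feature provenance do not match")
  mu <- colMeans(tr$values)
  sd_ <- apply(tr$values, 2, stats::sd)
  keep <- sd_ > 0
  dropped <- tr$provenance[!keep]
  scale_fm <- function(fm) {
    v <- sweep(sweep(fm$values[, keep, drop = FALSE], 2, mu[keep]),
               2, sd_[keep], "/")
    feature_matrix(v, fm$labels, fm$provenance[keep])
  }
  list(train = scale_fm(tr), test = scale_fm(te),
       params = list(mean = mu[keep], sd = sd_[keep], dropped = dropped))
}

#' Median-ratio feature selection
#'
#' Scores each feature by the ratio of its class-conditional medians of
#' absolute values, `R = max(m1/m2, m2/m1)` (a machine-scale epsilon keeps
#' the ratio defined for signed, near-zero features), and keeps the top `k`
#' features; ties break deterministically by feature index.
#'
#' @param train_feats a [feature_matrix()] with two classes.
#' @param k number of features to keep (default 50).
#' @return A `selection_mask`: `indices` (sorted, length `k`) and per-feature
#'   `scores`.
#' @export
median_ratio_select <- function(train_feats, k = 50) {
  if (k > ncol(train_feats$values))
    stop("k exceeds the feature count")
  classes <- intersect(c("C", "NC"), unique(train_feats$labels))
  if (length(classes) < 2) classes <- sort(unique(train_feats$labels))
  if (length(classes) != 2) stop("need exactly two classes")
  eps <- .Machine$double.eps
  m1 <- apply(abs(train_feats$values[train_feats$labels == classes[1], ,
                                     drop = FALSE]), 2, stats::median) + eps
  m2 <- apply(abs(train_feats$values[train_feats$labels == classes[2], ,
                                     drop = FALSE]), 2, stats::median) + eps
  score <- pmax(m1 / m2, m2 / m1)
  idx <- sort(order(-score, seq_along(score))[seq_len(k)])
  structure(list(indices = idx, scores = score), class = "selection_mask")
}

#' Apply a selection mask to a feature matrix
#'
#' @param feats a [feature_matrix()].
#' @param mask a `selection_mask` from [median_ratio_select()].
#' @return The restricted [feature_matrix()].
#' @export
apply_mask <- function(feats, mask) {
  feature_matrix(feats$values[, mask$indices, drop = FALSE], feats$labels,
                 feats$provenance[mask$indices])
}
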