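#' Zero-phase Butterworth band-pass of an epoch set or session
#'
#' Order-3 Butterworth by default, applied forwards and backwards. Used to
#' isolate the canonical delta/theta/alpha/beta bands before spatio-spectral
#' filtering.
#'
#' @param epochs an [epoch_set()] or [raw_session()].
#' @param band length-2 numeric, band edges in Hz.
#' @param order Butterworth order (per pass).
#' @return Same class as the input, band-pass filtered.
#' @export
butter_band <- function(epochs, band, order = 3) {
  if (length(band) != 2 || band[1] <= 0 || band[1] >= band[2])
    stop("band must be an increasing positive Hz pair")
  bandpass_filter(epochs, high_pass = band[1], low_pass = band[2],
                  order = order)
}

# Delay-embed a channels x samples matrix: stack a tau-shifted copy of the
# channels, trimming tau samples so rows align. tau = 0 returns the input.
delay_augment <- function(X, tau) {
  if (tau == 0) return(X)
  T_ <- ncol(X)
  if (tau >= T_) stop("delay exceeds the window length")
  rbind(X[, 1:(T_ - tau), drop = FALSE],
        X[, (tau + 1):T_, drop = FALSE])
}

#' Fit common spatio-spectral pattern (CSSP) filters
#'
#' CSP on a delay-embedded channel set: each trial's channels are augmented
#' with a copy delayed by `delay` samples (giving every spatial filter one
#' free FIR tap, hence a spectral degree of freedom), per-trial spatial
#' covariances are trace-normalized and averaged per class, and the joint
#' diagonalization eigenproblem of the class covariances is solved. The
#' `n_pairs` highest- and `n_pairs` lowest-eigenvalue filters are retained;
#' each satisfies the whitening convention `w' (C1 + C2) w = 1`. With
#' `delay = 0` this is exactly standard CSP.
#'
#' @param train an [epoch_set()], already band-pass filtered and cropped to
#'   the analysis window.
#' @param band the Hz pair the input was filtered to (stored as metadata).
#' @param n_pairs number of filter pairs (default 3, i.e. 6 components).
#' @param delay embedding delay in samples (>= 0).
#' @return A `spatial_filter_bank` with `method = "CSSP"`; `weights` has
#'   `channels * 2` rows when `delay > 0`.
#' @export
fit_cssp <- function(train, band = NULL, n_pairs = 3, delay = 1) {
  if (delay < 0) stop("delay must be >= 0")
  classes <- intersect(c("C", "NC"), unique(train$labels))
  if (length(classes) < 2) classes <- sort(unique(train$labels))
  if (length(classes) < 2) stop("need two classes")
  covs <- lapply(classes, function(cl) {
    idx <- which(train$labels == cl)
    acc <- NULL
    for (i in idx) {
      A <- delay_augment(train$data[i, , ], delay)
      Ci <- tcrossprod(A)
      Ci <- Ci / sum(diag(Ci))
      acc <- if (is.null(acc)) Ci else acc + Ci
    }
    acc / length(idx)
  })
  Cc <- covs[[1]] + covs[[2]]
  ec <- eigen((Cc + t(Cc)) / 2, symmetric = TRUE)
  if (min(ec$values) < 1e-10 * max(ec$values))
    stop("rank-deficient class covariances; regularize or widen the window")
  Wh <- ec$vectors %*% diag(1 / sqrt(ec$values))
  S1 <- crossprod(Wh, covs[[1]]) %*% Wh
  e <- eigen((S1 + t(S1)) / 2, symmetric = TRUE)
  m <- length(e$values)
  if (2 * n_pairs > m) stop("n_pairs too large for the channel count")
  sel <- c(seq_len(n_pairs), m - n_pairs + seq_len(n_pairs))
  W <- Wh %*% e$vectors[, sel, drop = FALSE]
  structure(
    list(weights = fix_sign(W, normalize = FALSE),
         eigenvalues = e$values[sel],
         method = "CSSP", band = band, delay = as.integer(delay),
         channel_labels = train$channel_labels,
         classes = classes),
    class = "spatial_filter_bank")
}
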