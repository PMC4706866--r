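#' Per-condition average ERP waveforms
#'
#' Trial-mean waveform per condition (channels x samples), optionally
#' collapsed across channels, with the epoch time axis.
#'
#' @param epochs an [epoch_set()].
#' @param collapse_channels if `TRUE`, also return the channel-mean trace.
#' @return List with `times`, `conditions` (named list of channels x samples
#'   matrices) and, when requested, `grand` (named list of vectors).
#' @export
erp_average <- function(epochs, collapse_channels = TRUE) {
  conds <- unique(epochs$labels)
  per_cond <- lapply(conds, function(cl) {
    idx <- which(epochs$labels == cl)
    m <- apply(epochs$data[idx, , , drop = FALSE], c(2, 3), mean)
    rownames(m) <- epochs$channel_labels
    m
  })
  names(per_cond) <- conds
  out <- list(times = epochs$times, conditions = per_cond)
  if (collapse_channels)
    out$grand <- lapply(per_cond, colMeans)
  out
}

#' Event-related spectral perturbation (ERSP)
#'
#' Hann-windowed short-time Fourier power per trial (0.5 s windows, 93.75%
#' overlap by default), averaged across trials per condition and expressed
#' in dB relative to the mean pre-stimulus baseline power per frequency.
#' Stationary signals therefore map to ~0 dB everywhere and overall
#' amplitude scaling cancels.
#'
#' @param epochs an [epoch_set()].
#' @param channel channel label to analyze (default `"Pz"` when present,
#'   else the first channel).
#' @param baseline_window seconds pair inside the epoch span (default the
#'   pre-stimulus second).
#' @param freq_range frequencies to keep, Hz.
#' @param window_sec STFT window length in seconds.
#' @param overlap_frac fractional window overlap.
#' @return List with `times` (window centers, s), `freqs` (Hz), and `maps`:
#'   one frequencies x times dB matrix per condition.
#' @export
ersp <- function(epochs, channel = NULL, baseline_window = c(-1, 0),
                 freq_range = c(1, 25), window_sec = 0.5,
                 overlap_frac = 0.9375) {
  if (is.null(channel))
    channel <- if ("Pz" %in% epochs$channel_labels) "Pz" else
      epochs$channel_labels[1]
  ch <- match(channel, epochs$channel_labels)
  if (is.na(ch)) stop("unknown channel: ", channel)
  fs <- epochs$sampling_rate
  nw <- round(window_sec * fs)
  step <- max(1, round(nw * (1 - overlap_frac)))
  n_samp <- dim(epochs$data)[3]
  starts <- seq(1, n_samp - nw + 1, by = step)
  centers <- epochs$times[starts] + (nw - 1) / (2 * fs)
  if (baseline_window[1] < epochs$times[1] - 1e-9 ||
      baseline_window[2] > max(epochs$times) + 1e-9)
    stop("baseline window lies outside the epoch span")
  base_cols <- centers >= baseline_window[1] & centers <= baseline_window[2]
  if (!any(base_cols))
    stop("no STFT window falls inside the baseline window")
  win <- 0.5 * (1 - cos(2 * pi * (0:(nw - 1)) / (nw - 1)))
  freqs <- (0:(nw %/% 2)) * fs / nw
  keep_f <- freqs >= freq_range[1] & freqs <= freq_range[2]
  conds <- unique(epochs$labels)
  maps <- lapply(conds, function(cl) {
    idx <- which(epochs$labels == cl)
    acc <- matrix(0, sum(keep_f), length(starts))
    for (i in idx) {
      x <- epochs$data[i, ch, ]
      frames <- vapply(starts, function(s0) x[s0:(s0 + nw - 1)] * win,
                       numeric(nw))
      sp <- stats::mvfft(frames)
      p <- abs(sp[seq_len(nw %/% 2 + 1), , drop = FALSE])^2
      acc <- acc + p[keep_f, , drop = FALSE]
    }
    pw <- acc / length(idx)
    base <- rowMeans(pw[, base_cols, drop = FALSE])
    10 * log10(sweep(pw, 1, base, "/"))
  })
  names(maps) <- conds
  list(times = centers, freqs = freqs[keep_f], maps = maps,
       channel = channel)
}
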