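# Zero-phase (forward-backward) IIR filtering of every column of a matrix.
filtfilt_mat <- function(filt, x) {
  for (j in seq_len(ncol(x)))
    x[, j] <- signal::filtfilt(filt, x[, j])
  x
}

#' Zero-phase band-pass filter
#'
#' Applies a Butterworth band-pass (default 0.5-25 Hz: high-pass to correct
#' DC drift, low-pass to exclude muscle-dominated frequencies) forwards and
#' backwards, so ERP latencies are not shifted.
#'
#' @param x a [raw_session()] or [epoch_set()].
#' @param high_pass high-pass cutoff in Hz.
#' @param low_pass low-pass cutoff in Hz.
#' @param order Butterworth order (per pass).
#' @return An object of the same class as `x`, same shape, filtered.
#' @export
bandpass_filter <- function(x, high_pass = 0.5, low_pass = 25, order = 4) {
  UseMethod("bandpass_filter")
}

check_band <- function(high_pass, low_pass, fs) {
  if (!(0 < high_pass && high_pass < low_pass && low_pass < fs / 2))
    stop("cutoffs must satisfy 0 < high_pass < low_pass < sampling_rate/2")
}

#' @export
bandpass_filter.raw_session <- function(x, high_pass = 0.5, low_pass = 25,
                                        order = 4) {
  check_band(high_pass, low_pass, x$sampling_rate)
  bf <- signal::butter(order, c(high_pass, low_pass) / (x$sampling_rate / 2),
                       type = "pass")
  for (ch in seq_len(nrow(x$signal)))
    x$signal[ch, ] <- signal::filtfilt(bf, x$signal[ch, ])
  x
}

#' @export
bandpass_filter.epoch_set <- function(x, high_pass = 0.5, low_pass = 25,
                                      order = 4) {
  check_band(high_pass, low_pass, x$sampling_rate)
  bf <- signal::butter(order, c(high_pass, low_pass) / (x$sampling_rate / 2),
                       type = "pass")
  d <- dim(x$data)
  flat <- matrix(aperm(x$data, c(3, 1, 2)), nrow = d[3])
  x$data <- aperm(array(filtfilt_mat(bf, flat), dim = c(d[3], d[1], d[2])),
                  c(2, 3, 1))
  x
}

#' Extract stimulus-locked epochs
#'
#' Cuts one epoch per retained event, spanning `span` seconds around the
#' event marker. Events whose window would exceed the recording bounds are
#' dropped and recorded in the `"dropped_events"` attribute. The time axis is
#' anchored at the marker; the fixed display latency is accounted for later
#' by the feature-window start, not here.
#'
#' @param session a [raw_session()].
#' @param span length-2 numeric, seconds around onset (default `c(-1, 2.5)`).
#' @param conditions conditions to retain (default C and NC: FLAT control
#'   trials are excluded from classification).
#' @return An [epoch_set()]; attribute `"dropped_events"` holds the indices
#'   (within the retained-condition events) of boundary-dropped events.
#' @export
extract_epochs <- function(session, span = c(-1.0, 2.5),
                           conditions = c("C", "NC")) {
  if (span[1] >= span[2]) stop("span[1] must be < span[2]")
  fs <- session$sampling_rate
  off0 <- round(span[1] * fs)
  n_samp <- round((span[2] - span[1]) * fs)
  ev <- session$events[session$events$condition %in% conditions, ,
                       drop = FALSE]
  if (nrow(ev) == 0) stop("no events with the requested conditions")
  first <- ev$onset_sample + off0
  last <- first + n_samp - 1L
  ok <- first >= 1 & last <= ncol(session$signal)
  dropped <- which(!ok)
  ev <- ev[ok, , drop = FALSE]
  if (nrow(ev) == 0) stop("all epochs exceed the recording bounds")
  data <- array(0, dim = c(nrow(ev), nrow(session$signal), n_samp))
  for (i in seq_len(nrow(ev))) {
    i0 <- ev$onset_sample[i] + off0
    data[i, , ] <- session$signal[, i0:(i0 + n_samp - 1L)]
  }
  out <- epoch_set(data, ev$condition, times = (off0 + 0:(n_samp - 1)) / fs,
                   sampling_rate = fs,
                   channel_labels = session$channel_labels,
                   subject_id = session$subject_id)
  attr(out, "dropped_events") <- dropped
  out
}

#' Automated artifact-epoch rejection
#'
#' Iteratively rejects epochs whose peak absolute amplitude exceeds
#' `abs_threshold` or whose per-epoch variance is a robust outlier
#' (|variance - median| / MAD above `z_threshold`, MAD across the surviving
#' epochs), until no further epoch is rejected. A threshold-based surrogate
#' for automated muscular-artifact rejection.
#'
#' @param epochs an [epoch_set()].
#' @param abs_threshold absolute amplitude bound in microvolts.
#' @param z_threshold robust variance z-score bound.
#' @return A list with `epochs` (cleaned) and `log`, a `rejection_log` with
#'   `rejected_indices` (into the input), per-index `reasons`
#'   (`"amplitude"` or `"variance"`), and the thresholds used.
#' @export
reject_artifact_epochs <- function(epochs, abs_threshold = 150,
                                   z_threshold = 5) {
  if (abs_threshold <= 0 || z_threshold <= 0)
    stop("thresholds must be > 0")
  n <- n_trials(epochs)
  peak <- vapply(seq_len(n), function(i)
    max(abs(epochs$data[i, , ])), numeric(1))
  v <- vapply(seq_len(n), function(i)
    stats::var(as.vector(epochs$data[i, , ])), numeric(1))
  keep <- rep(TRUE, n)
  reason <- character(n)
  repeat {
    new_amp <- keep & peak > abs_threshold
    med <- stats::median(v[keep & !new_amp])
    md <- stats::mad(v[keep & !new_amp])
    new_var <- keep & !new_amp &
      (if (isTRUE(md > 0)) abs(v - med) / md > z_threshold else FALSE)
    if (!any(new_amp | new_var)) break
    reason[new_amp] <- "amplitude"
    reason[new_var] <- "variance"
    keep <- keep & !(new_amp | new_var)
    if (!any(keep))
      stop("all epochs rejected: thresholds are degenerate for this data")
  }
  log <- structure(
    list(rejected_indices = which(!keep), reasons = reason[!keep],
         abs_threshold = abs_threshold, z_threshold = z_threshold),
    class = "rejection_log")
  list(epochs = subset_trials(epochs, which(keep)), log = log)
}

#' @export
print.rejection_log <- function(x, ...) {
  cat(sprintf("<rejection_log> %d epoch(s) rejected (abs > %g muV: %d, variance z > %g: %d)\n",
              length(x$rejected_indices), x$abs_threshold,
              sum(x$reasons == "amplitude"), x$z_threshold,
              sum(x$reasons == "variance")))
  invisible(x)
}

#' Select and reorder channels
#'
#' @param epochs an [epoch_set()].
#' @param names channel labels to retain, in the desired order.
#' @return An [epoch_set()] restricted to `names`.
#' @export
select_channels <- function(epochs, names) {
  missing <- setdiff(names, epochs$channel_labels)
  if (length(missing))
    stop("unknown channel label(s): ", paste(missing, collapse = ", "))
  idx <- match(names, epochs$channel_labels)
  epoch_set(epochs$data[, idx, , drop = FALSE], epochs$labels, epochs$times,
            epochs$sampling_rate, names, epochs$subject_id)
}
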