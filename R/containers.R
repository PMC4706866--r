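#' Continuous multichannel EEG session
#'
#' Container for one subject's continuous recording: a channels-by-samples
#' signal matrix in microvolts, the sampling rate, channel labels and a table
#' of stimulus events.
#'
#' @param signal numeric matrix, channels x samples (microvolts).
#' @param sampling_rate sampling rate in Hz.
#' @param channel_labels character vector, one label per signal row.
#' @param events data.frame with columns `onset_sample` (1-based index into
#'   the sample axis) and `condition` (one of `"C"`, `"NC"`, `"FLAT"`).
#' @param subject_id subject identifier.
#' @return An object of class `raw_session`.
#' @export
raw_session <- function(signal, sampling_rate, channel_labels, events,
                        subject_id = "S01") {
  signal <- as.matrix(signal)
  channel_labels <- as.character(channel_labels)
  if (nrow(signal) != length(channel_labels))
    stop("signal has ", nrow(signal), " rows but ", length(channel_labels),
         " channel labels were given")
  if (anyDuplicated(channel_labels))
    stop("channel labels must be unique")
  events <- as.data.frame(events)
  if (!all(c("onset_sample", "condition") %in% names(events)))
    stop("events must have columns 'onset_sample' and 'condition'")
  bad <- setdiff(unique(events$condition), c("C", "NC", "FLAT"))
  if (length(bad))
    stop("unknown condition(s): ", paste(bad, collapse = ", "))
  if (any(events$onset_sample < 1 | events$onset_sample > ncol(signal)))
    stop("event onsets fall outside the recording")
  events <- events[order(events$onset_sample), , drop = FALSE]
  rownames(events) <- NULL
  structure(
    list(signal = signal, sampling_rate = sampling_rate,
         channel_labels = channel_labels, events = events,
         subject_id = subject_id),
    class = "raw_session")
}

#' @export
print.raw_session <- function(x, ...) {
  cat(sprintf("<raw_session> subject %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, nrow(x$signal), ncol(x$signal), x$sampling_rate,
              ncol(x$signal) / x$sampling_rate))
  cat("  events:", paste(sprintf("%s=%d", names(table(x$events$condition)),
                                 table(x$events$condition)), collapse = ", "), "\n")
  invisible(x)
}

#' Epoched EEG trials
#'
#' Trials x channels x samples array with per-trial condition labels and a
#' time axis in seconds relative to stimulus onset.
#'
#' @param data numeric array, trials x channels x samples (microvolts).
#' @param labels character vector of per-trial conditions.
#' @param times numeric vector of per-sample times (s), strictly increasing.
#' @param sampling_rate sampling rate in Hz.
#' @param channel_labels character vector of channel names.
#' @param subject_id subject identifier.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, labels, times, sampling_rate, channel_labels,
                      subject_id = "S01") {
  stopifnot(length(dim(data)) == 3)
  if (dim(data)[1] != length(labels))
    stop("label count does not match trial count")
  if (dim(data)[2] != length(channel_labels))
    stop("channel label count does not match channel dimension")
  if (dim(data)[3] != length(times))
    stop("time axis length does not match sample dimension")
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing")
  structure(
    list(data = data, labels = as.character(labels), times = times,
         sampling_rate = sampling_rate,
         channel_labels = as.character(channel_labels),
         subject_id = subject_id),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> subject %s: %d trials x %d channels x %d samples [%.3f, %.3f] s\n",
              x$subject_id, d[1], d[2], d[3], min(x$times), max(x$times)))
  cat("  labels:", paste(sprintf("%s=%d", names(table(x$labels)),
                                 table(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

#' Number of trials in an epoch set
#'
#' @param epochs an [epoch_set()].
#' @return Integer trial count.
#' @export
n_trials <- function(epochs) dim(epochs$data)[1]

# Subset an epoch_set by trial index, keeping bookkeeping aligned.
subset_trials <- function(epochs, idx) {
  epoch_set(epochs$data[idx, , , drop = FALSE], epochs$labels[idx],
            epochs$times, epochs$sampling_rate, epochs$channel_labels,
            epochs$subject_id)
}

# Crop an epoch_set to a time window [t0, t0 + length) (seconds).
crop_epochs <- function(epochs, window_start, window_length) {
  keep <- epochs$times >= window_start &
    epochs$times < window_start + window_length
  if (!any(keep))
    stop("time window [", window_start, ", ", window_start + window_length,
         ") does not overlap the epoch span")
  epoch_set(epochs$data[, , keep, drop = FALSE], epochs$labels,
            epochs$times[keep], epochs$sampling_rate, epochs$channel_labels,
            epochs$subject_id)
}
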