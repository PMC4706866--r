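# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so generation does not perturb user code.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

# Gaussian-random signal with a prescribed amplitude spectrum, built by
# shaping complex white spectra and inverse FFT (length padded to a
# 2-3-5-smooth size). `shape_fun(f)` gives relative spectral amplitude at
# frequency f (Hz); random coefficients are only drawn where the amplitude
# is non-zero, so narrowband shapes are cheap.
spectral_noise <- function(n, fs, shape_fun) {
  m <- stats::nextn(max(n, 16), c(2, 3, 5))
  while (m %% 2 == 1) m <- stats::nextn(m + 1, c(2, 3, 5))
  nf <- m %/% 2
  f <- (1:(nf - 1)) * fs / m
  amp <- shape_fun(f)
  nz <- which(amp > 0)
  sp <- complex(real = numeric(nf - 1), imaginary = numeric(nf - 1))
  sp[nz] <- complex(real = stats::rnorm(length(nz)),
                    imaginary = stats::rnorm(length(nz))) * amp[nz]
  full <- c(0, sp, 0, Conj(rev(sp)))
  Re(stats::fft(full, inverse = TRUE))[seq_len(n)] / sqrt(m)
}

# 1/f amplitude shape with a low-frequency floor (keeps drift finite) and
# a high-frequency cutoff: synthesized content stays well below Nyquist,
# and the analysis band-pass removes everything above `cut_hz` anyway.
pink_shape <- function(exponent, floor_hz = 0.3, cut_hz = 45) {
  function(f) {
    a <- pmax(f, floor_hz)^(-exponent / 2)
    a[f > cut_hz] <- 0
    a
  }
}

# Flat in [lo, hi] with raised-cosine roll-off edges (Hz).
band_shape <- function(lo, hi, roll = 1) {
  function(f) {
    a <- numeric(length(f))
    a[f >= lo & f <= hi] <- 1
    rise <- f > lo - roll & f < lo
    a[rise] <- 0.5 * (1 + cos(pi * (lo - f[rise]) / roll))
    fall <- f > hi & f < hi + roll
    a[fall] <- 0.5 * (1 + cos(pi * (f[fall] - hi) / roll))
    a
  }
}

# scale a zero-mean signal to a target RMS (no-op on all-zero input)
scale_rms <- function(x, target) {
  s <- stats::sd(x)
  if (s == 0 || target == 0) return(x * 0)
  x * (target / s)
}

# Trial timing: cross U(1, 1.5) s, object U(2.5, 3) s, task 1.5 s
# (mean trial 5.5 s). Returns object-onset times (s) and total duration.
draw_trial_timing <- function(n_trials, lead_in = 2, tail = 3) {
  cross <- stats::runif(n_trials, 1.0, 1.5)
  object <- stats::runif(n_trials, 2.5, 3.0)
  task <- rep(1.5, n_trials)
  starts <- lead_in + cumsum(c(0, (cross + object + task)[-n_trials]))
  onsets <- starts + cross
  list(onsets = onsets, duration = lead_in + sum(cross + object + task) + tail)
}

#' Generate one synthetic EEG session
#'
#' Synthesizes a continuous multichannel recording with the signal structure
#' the downstream classifier exploits: a 1/f broadband background, continuous
#' alpha- and theta-band oscillatory streams, a stimulus-locked positive ERP
#' deflection whose peak is larger in the comfortable ("C") condition, and a
#' post-stimulus amplitude modulation of the oscillatory streams
#' (alpha suppressed, theta enhanced) in the uncomfortable ("NC") condition.
#' "FLAT" (2D control) trials carry the average of the C/NC generative
#' parameters. Events for all three conditions are spaced ~5.5 s apart with
#' uniform jitter, and the evoked response lags each marker by the configured
#' display latency.
#'
#' @param config a `synth_config`, see [make_default_config()].
#' @param subject_id subject identifier stored in the output.
#' @param seed integer seed; equal (config, seed) give identical sessions.
#' @return A [raw_session()].
#' @export
generate_session <- function(config, subject_id = "S01", seed = config$seed) {
  validate_config(config)
  with_seed(seed, {
    fs <- config$sampling_rate
    n_per <- config$n_trials_per_condition
    n_tot <- 3L * n_per
    conditions <- sample(rep(c("C", "NC", "FLAT"), each = n_per))
    timing <- draw_trial_timing(n_tot)
    n <- ceiling(timing$duration * fs)
    onset_samples <- round(timing$onsets * fs) + 1L

    labels <- config$eeg_channels
    n_ch <- length(labels)
    topo <- config$erp_topography
    if (is.null(topo)) topo <- .region_weight(labels, "posterior")
    if (length(topo) != n_ch)
      stop("erp_topography must have one weight per channel")
    alpha_w <- .region_weight(labels, "posterior")
    theta_w <- .region_weight(labels, "frontal")

    # per-condition band-amplitude envelopes (shared across channels):
    # 1 everywhere except the NC/FLAT modulation window post-appearance
    app_samples <- onset_samples + round(config$display_latency * fs)
    alpha_env <- rep(1, n)
    theta_env <- rep(1, n)
    ramp_len <- round(0.1 * fs)
    ramp <- 0.5 * (1 - cos(pi * seq_len(ramp_len) / ramp_len))
    mod_span <- c(config$modulation_onset, config$epoch_span[2])
    for (i in seq_len(n_tot)) {
      if (conditions[i] == "C") next
      ga <- config$alpha_gain_NC
      gt <- config$theta_gain_NC
      if (conditions[i] == "FLAT") {
        ga <- (1 + ga) / 2
        gt <- (1 + gt) / 2
      }
      i0 <- app_samples[i] + round(mod_span[1] * fs)
      i1 <- min(app_samples[i] + round(mod_span[2] * fs), n)
      if (i0 >= i1) next
      idx <- i0:i1
      prof <- rep(1, length(idx))
      k <- min(ramp_len, length(idx))
      prof[seq_len(k)] <- ramp[seq_len(k)]
      prof[length(idx) + 1 - seq_len(k)] <- pmin(
        prof[length(idx) + 1 - seq_len(k)], ramp[seq_len(k)])
      alpha_env[idx] <- 1 + (ga - 1) * prof
      theta_env[idx] <- 1 + (gt - 1) * prof
    }

    # ERP kernel: Gaussian-windowed positive deflection after appearance
    k_len <- round((config$erp_latency + 4 * config$erp_width) * fs)
    kt <- (seq_len(k_len) - 1) / fs
    kern <- exp(-0.5 * ((kt - config$erp_latency) / config$erp_width)^2)
    amp_of <- c(C = config$erp_base_amp + config$erp_peak_gain_C,
                NC = config$erp_base_amp,
                FLAT = config$erp_base_amp + config$erp_peak_gain_C / 2)

    pink <- pink_shape(config$noise_exponent)
    a_shape <- band_shape(config$alpha_band[1], config$alpha_band[2])
    t_shape <- band_shape(config$theta_band[1], config$theta_band[2])

    # oscillatory streams are spatially coherent sources: one narrowband
    # process per band, projected to the scalp through a fixed topography
    # (posterior for alpha, fronto-central for theta); the 1/f background
    # is independent per channel
    alpha_src <- scale_rms(spectral_noise(n, fs, a_shape), 1) * alpha_env
    theta_src <- scale_rms(spectral_noise(n, fs, t_shape), 1) * theta_env
    sig <- matrix(0, n_ch, n)
    for (ch in seq_len(n_ch)) {
      sig[ch, ] <- scale_rms(spectral_noise(n, fs, pink),
                             config$noise_scale) +
        (config$alpha_scale * alpha_w[ch]) * alpha_src +
        (config$theta_scale * theta_w[ch]) * theta_src
    }
    for (i in seq_len(n_tot)) {
      idx <- app_samples[i]:min(app_samples[i] + k_len - 1L, n)
      sig[, idx] <- sig[, idx] +
        (amp_of[[conditions[i]]] * topo) %o% kern[seq_along(idx)]
    }

    session <- raw_session(
      signal = sig, sampling_rate = fs, channel_labels = labels,
      events = data.frame(onset_sample = onset_samples,
                          condition = conditions,
                          stringsAsFactors = FALSE),
      subject_id = subject_id)
    if (config$blink_rate > 0)
      session <- inject_blinks(session, config$blink_rate,
                               seed = seed + 7919L)
    session
  })
}

#' Per-subject generative configurations of a cohort
#'
#' Derives one perturbed configuration per subject: the ERP peak gain and the
#' alpha/theta band gains are scaled by independent log-normal multipliers
#' with log-SD `inter_subject_sd` (band gains are perturbed on the log-gain
#' scale, preserving their direction). Subject seeds are `config$seed +
#' subject index`; multipliers are drawn from a separate stream seeded with
#' `config$seed` so they do not interact with session noise.
#'
#' @param config a `synth_config`.
#' @return A list with one element per subject: `config`, `subject_id`, `seed`.
#' @export
cohort_configs <- function(config) {
  validate_config(config)
  if (config$n_subjects < 1) stop("n_subjects must be >= 1")
  mult <- with_seed(config$seed,
    matrix(exp(stats::rnorm(3 * config$n_subjects, 0,
                            config$inter_subject_sd)),
           ncol = 3))
  lapply(seq_len(config$n_subjects), function(s) {
    cfg <- config
    cfg$erp_peak_gain_C <- config$erp_peak_gain_C * mult[s, 1]
    cfg$alpha_gain_NC <- config$alpha_gain_NC^mult[s, 2]
    cfg$theta_gain_NC <- config$theta_gain_NC^mult[s, 3]
    list(config = cfg,
         subject_id = sprintf("S%02d", s),
         seed = config$seed + s)
  })
}

#' Generate a synthetic EEG cohort
#'
#' One session per subject, with per-subject effect sizes perturbed as
#' described in [cohort_configs()]. With `inter_subject_sd = 0` all subjects
#' share identical effect parameters (their noise realizations still differ).
#'
#' @param config a `synth_config`.
#' @return List of [raw_session()] objects.
#' @export
generate_cohort <- function(config) {
  lapply(cohort_configs(config), function(sc)
    generate_session(sc$config, sc$subject_id, sc$seed))
}

# raised-cosine blink bump, `duration` seconds wide
blink_kernel <- function(fs, duration = 0.35) {
  k_len <- round(duration * fs)
  0.5 * (1 - cos(2 * pi * seq_len(k_len) / (k_len + 1)))
}

# resolve a per-channel blink weighting profile (frontal-dominant default)
blink_weights <- function(channel_labels, weights) {
  if (is.null(weights)) return(.region_weight(channel_labels, "frontal"))
  bad <- setdiff(names(weights), channel_labels)
  if (length(bad))
    stop("unknown channel label(s) in weighting profile: ",
         paste(bad, collapse = ", "))
  w <- numeric(length(channel_labels))
  w[match(names(weights), channel_labels)] <- weights
  w
}

#' Add stereotyped blink artifacts
#'
#' Superimposes smooth, large, low-frequency transients (~350 ms raised
#' cosine bumps) at Poisson-distributed times, weighted toward frontal
#' channels. The input object is not modified. The [raw_session()] method
#' injects into the continuous recording; the [epoch_set()] method injects
#' independently into each epoch (expected blink count per epoch follows
#' from `rate` and the epoch duration) and can band-limit the blink
#' waveform first, for use with epochs that have already been filtered.
#'
#' @param x a [raw_session()] or [epoch_set()].
#' @param rate blink rate in events per minute.
#' @param seed integer seed.
#' @param amplitude peak amplitude in microvolts at the most frontal site.
#' @param duration blink duration in seconds.
#' @param weights optional named per-channel weight profile; names must all
#'   be channels of `x`. Default: frontal-dominant profile derived from the
#'   10-20 labels.
#' @param ... passed to methods.
#' @return An object of the same class with blinks added.
#' @export
inject_blinks <- function(x, rate, seed = 1L, amplitude = 180,
                          duration = 0.35, weights = NULL, ...) {
  UseMethod("inject_blinks")
}

#' @export
inject_blinks.raw_session <- function(x, rate, seed = 1L, amplitude = 180,
                                      duration = 0.35, weights = NULL, ...) {
  if (rate < 0) stop("rate must be >= 0")
  w <- blink_weights(x$channel_labels, weights)
  if (rate == 0) return(x)
  with_seed(seed, {
    fs <- x$sampling_rate
    n <- ncol(x$signal)
    n_blinks <- stats::rpois(1, rate * n / fs / 60)
    if (n_blinks > 0) {
      kern <- amplitude * blink_kernel(fs, duration)
      at <- sort(sample.int(n - length(kern), n_blinks, replace = TRUE))
      for (s0 in at) {
        idx <- s0:(s0 + length(kern) - 1L)
        x$signal[, idx] <- x$signal[, idx] + w %o% kern
      }
    }
    x
  })
}

#' @rdname inject_blinks
#' @param band optional `c(high_pass, low_pass)` Hz pair; when given, the
#'   blink waveform is zero-phase band-passed before injection, so it
#'   carries only the frequency content that survives the recording
#'   band-pass.
#' @export
inject_blinks.epoch_set <- function(x, rate, seed = 1L, amplitude = 180,
                                    duration = 0.35, weights = NULL,
                                    band = NULL, ...) {
  if (rate < 0) stop("rate must be >= 0")
  w <- blink_weights(x$channel_labels, weights)
  if (rate == 0) return(x)
  fs <- x$sampling_rate
  kern <- amplitude * blink_kernel(fs, duration)
  if (!is.null(band)) {
    pad <- round(0.75 * fs)
    padded <- c(numeric(pad), kern, numeric(pad))
    bf <- signal::butter(4, band / (fs / 2), type = "pass")
    kern <- signal::filtfilt(bf, padded)
  }
  with_seed(seed, {
    n_samp <- dim(x$data)[3]
    span_min <- n_samp / fs / 60
    for (i in seq_len(n_trials(x))) {
      n_blinks <- stats::rpois(1, rate * span_min)
      if (n_blinks == 0) next
      centers <- sample.int(n_samp, n_blinks, replace = TRUE)
      for (cc in centers) {
        i0 <- cc - length(kern) %/% 2
        j <- max(1, 2 - i0):min(length(kern), n_samp - i0 + 1)
        x$data[i, , i0 + j - 1] <- x$data[i, , i0 + j - 1] +
          w %o% kern[j]
      }
    }
    x
  })
}
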