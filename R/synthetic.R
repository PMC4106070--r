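# Synthetic multichannel EEG with the statistical structure the detector
# assumes: pink-noise background with a shared common-mode component,
# seizure windows carrying a coherent band-limited oscillation on a subset
# of channels, and rare high-amplitude EMG-like bursts in both classes.

#' Configuration for the synthetic EEG generator
#'
#' Defaults describe a scalp-EEG-like regime: 8 channels at 256 Hz, a 10 uV
#' RMS pink-noise background, an alpha-band (8-13 Hz) ictal oscillation of
#' 25 uV shared (with small phase jitter) by three quarters of the channels,
#' and EMG-like bursts arriving at 3 per minute with 20x the background
#' amplitude for 0.3 s.  Bursts are injected at the same rate in both
#' classes, so they are uninformative about the label by construction.
#'
#' @param n_channels number of channels (default 8).
#' @param fs sampling rate in Hz (default 256).
#' @param background_amp RMS amplitude of the background noise in uV.
#' @param seizure_band `c(lb, ub)` Hz band containing the ictal oscillation.
#' @param seizure_amp amplitude of the coherent oscillation in uV.
#' @param coupled_fraction fraction of channels carrying the oscillation.
#' @param artifact_rate expected EMG bursts per minute.
#' @param artifact_amp_mult burst amplitude as a multiple of `background_amp`.
#' @param artifact_dur_s burst duration in seconds.
#' @param common_mode_frac relative amplitude of the shared background
#'   component (keeps baseline cross-power away from zero).
#' @param seed integer seed used by [make_labeled_dataset()].
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_channels = 8L, fs = 256, background_amp = 10,
                         seizure_band = c(8, 13), seizure_amp = 25,
                         coupled_fraction = 0.75, artifact_rate = 3,
                         artifact_amp_mult = 20, artifact_dur_s = 0.3,
                         common_mode_frac = 0.3, seed = 1L) {
  stopifnot(n_channels >= 1, fs > 0,
            length(seizure_band) == 2L,
            0 < seizure_band[1L], seizure_band[1L] < seizure_band[2L],
            seizure_band[2L] < fs / 2,
            background_amp >= 0, seizure_amp >= 0,
            coupled_fraction > 0, coupled_fraction <= 1,
            artifact_rate >= 0, artifact_amp_mult >= 0, artifact_dur_s > 0)
  structure(
    list(n_channels = as.integer(n_channels), fs = fs,
         background_amp = background_amp, seizure_band = seizure_band,
         seizure_amp = seizure_amp, coupled_fraction = coupled_fraction,
         artifact_rate = artifact_rate, artifact_amp_mult = artifact_amp_mult,
         artifact_dur_s = artifact_dur_s, common_mode_frac = common_mode_frac,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

# One unit-variance pink-noise trace of n samples: white noise spectrally
# shaped by 1/sqrt(f) and renormalised to unit standard deviation.
pink_noise <- function(n) {
  z <- rnorm(n)
  zf <- fft(z)
  k <- 0:(n - 1L)
  m <- pmin(k, n - k)                        # symmetric frequency index
  m[1L] <- 1                                 # keep DC bin, do not amplify
  shaped <- Re(fft(zf / sqrt(m), inverse = TRUE)) / n
  s <- sd(shaped)
  if (s > 0) shaped / s else shaped
}

#' Generate background (inter-ictal) multichannel activity
#'
#' Each channel is unit-variance pink noise plus a shared pink common-mode
#' component of relative amplitude `common_mode_frac`, rescaled so the
#' per-channel standard deviation equals `background_amp`.
#'
#' @param config a [synth_config()].
#' @param duration_s duration in seconds (> 0).
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return `n_channels` x `round(duration_s * fs)` matrix in uV.
#' @export
gen_background <- function(config, duration_s, seed = NULL) {
  stopifnot(inherits(config, "synth_config"), duration_s > 0)
  with_seed(seed, {
    n <- round(duration_s * config$fs)
    cm <- config$common_mode_frac
    shared <- pink_noise(n)
    scale <- config$background_amp / sqrt(1 + cm^2)
    data <- matrix(0, config$n_channels, n)
    for (c in seq_len(config$n_channels)) {
      data[c, ] <- scale * (pink_noise(n) + cm * shared)
    }
    data
  })
}

#' Generate ictal multichannel activity
#'
#' Background activity plus a sinusoid whose instantaneous frequency drifts
#' slowly inside `seizure_band`, placed with a common phase (up to a small
#' per-channel jitter) on `ceiling(coupled_fraction * n_channels)` randomly
#' chosen channels.  With `seizure_amp = 0` the output equals
#' [gen_background()] under the same seed.
#'
#' @inheritParams gen_background
#' @return `n_channels` x samples matrix in uV; the attribute
#'   `"coupled_channels"` records which channels carry the oscillation.
#' @export
gen_seizure_activity <- function(config, duration_s, seed = NULL) {
  stopifnot(inherits(config, "synth_config"), duration_s > 0)
  with_seed(seed, {
    data <- gen_background(config, duration_s)
    n <- ncol(data)
    t <- (seq_len(n) - 1L) / config$fs
    lb <- config$seizure_band[1L]; ub <- config$seizure_band[2L]
    half_sweep <- 0.15 * (ub - lb)
    f0 <- runif(1L, lb + half_sweep, ub - half_sweep)
    fmod <- runif(1L, 0.1, 0.3)              # Hz, slow drift
    phase0 <- runif(1L, 0, 2 * pi)
    # instantaneous frequency f0 + half_sweep * sin(2 pi fmod t); integrate
    inst_phase <- 2 * pi * (f0 * t - half_sweep / (2 * pi * fmod) *
                              (cos(2 * pi * fmod * t) - 1)) + phase0
    k <- ceiling(config$coupled_fraction * config$n_channels)
    coupled <- sort(sample.int(config$n_channels, k))
    for (c in coupled) {
      jitter <- rnorm(1L, 0, 0.1)
      data[c, ] <- data[c, ] + config$seizure_amp * sin(inst_phase + jitter)
    }
    attr(data, "coupled_channels") <- coupled
    data
  })
}

#' Inject EMG-like bursts into a multichannel signal
#'
#' Bursts arrive as a Poisson process with `artifact_rate` events per
#' minute.  Each event adds high-pass-shaped noise (first difference of
#' white noise) under a Hann envelope of `artifact_dur_s` seconds, with RMS
#' amplitude `artifact_amp_mult * background_amp`, to 1-3 randomly chosen
#' channels.
#'
#' @param data channels x samples matrix.
#' @param config a [synth_config()].
#' @param seed optional integer seed.
#' @return list with elements `data` (modified copy) and `log`
#'   (data frame of `onset_s`, `channel` per burst-channel pair).
#' @export
inject_emg_artifacts <- function(data, config, seed = NULL) {
  stopifnot(is.matrix(data), inherits(config, "synth_config"))
  with_seed(seed, {
    fs <- config$fs
    n <- ncol(data)
    dur_s <- n / fs
    m <- round(config$artifact_dur_s * fs)
    n_events <- rpois(1L, config$artifact_rate * dur_s / 60)
    log <- data.frame(onset_s = numeric(0), channel = integer(0))
    if (n_events > 0L && m >= 2L && m <= n) {
      amp <- config$artifact_amp_mult * config$background_amp
      env <- 0.5 - 0.5 * cos(2 * pi * (seq_len(m) - 1L) / (m - 1L))
      for (e in seq_len(n_events)) {
        i0 <- sample.int(n - m + 1L, 1L)
        chans <- sample.int(nrow(data), sample.int(min(3L, nrow(data)), 1L))
        # one muscle source per event: a shared high-pass waveform reaches
        # each affected channel with its own coupling gain
        burst <- diff(c(0, rnorm(m)))
        burst <- burst / max(sd(burst), .Machine$double.eps) * amp * env
        for (c in chans) {
          gain <- runif(1L, 0.7, 1.3)
          data[c, i0:(i0 + m - 1L)] <- data[c, i0:(i0 + m - 1L)] + gain * burst
          log <- rbind(log, data.frame(onset_s = (i0 - 1L) / fs, channel = c))
        }
      }
    }
    list(data = data, log = log)
  })
}

#' Generate a labelled dataset of synthetic EEG segments
#'
#' Seizure segments are windows of [gen_seizure_activity()], nonseizure
#' segments windows of [gen_background()]; both classes receive EMG bursts
#' via [inject_emg_artifacts()] at the same rate.  The emitted list is
#' shuffled deterministically under `config$seed`.
#'
#' @param config a [synth_config()].
#' @param n_seizure number of seizure segments (> 0).
#' @param n_nonseizure number of nonseizure segments (> 0).
#' @param window_s segment length in seconds (default 5).
#' @param artifacts logical; inject EMG bursts into both classes.
#' @return list of labelled `eeg_segment` objects of length
#'   `n_seizure + n_nonseizure`.
#' @export
make_labeled_dataset <- function(config, n_seizure, n_nonseizure,
                                 window_s = 5, artifacts = TRUE) {
  stopifnot(inherits(config, "synth_config"))
  if (!is_count(n_seizure) || !is_count(n_nonseizure)) {
    stop_rsae("n_seizure and n_nonseizure must be positive counts")
  }
  with_seed(config$seed, {
    make_one <- function(label) {
      data <- if (label == "seizure") {
        gen_seizure_activity(config, window_s)
      } else {
        gen_background(config, window_s)
      }
      if (artifacts) data <- inject_emg_artifacts(data, config)$data
      attr(data, "coupled_channels") <- NULL
      new_segment(data, label, 0)
    }
    segs <- c(
      lapply(seq_len(n_seizure), function(i) make_one("seizure")),
      lapply(seq_len(n_nonseizure), function(i) make_one("nonseizure"))
    )
    segs[sample.int(length(segs))]
  })
}

#' Render a synthetic dataset as one annotated recording
#'
#' Concatenates segments along time (seizure segments become seizure
#' intervals), so the generator output can be written with
#' [write_recording()] or [write_edf()] and re-read with
#' [read_recording()] / [segment_recording()].
#'
#' @param segments list of labelled `eeg_segment` objects (equal lengths).
#' @param fs sampling rate in Hz.
#' @return an [recording()] object.
#' @export
segments_to_recording <- function(segments, fs) {
  stopifnot(length(segments) > 0L)
  data <- do.call(cbind, lapply(segments, function(s) s$data))
  L <- ncol(segments[[1L]]$data) / fs
  lab <- segment_labels(segments)
  starts <- (seq_along(segments) - 1L) * L
  ints <- cbind(starts[lab == "seizure"], starts[lab == "seizure"] + L)
  # merge touching intervals
  if (nrow(ints) > 1L) {
    keep <- list(ints[1L, ])
    for (k in 2L:nrow(ints)) {
      last <- keep[[length(keep)]]
      if (abs(ints[k, 1L] - last[2L]) < 1e-9) {
        keep[[length(keep)]][2L] <- ints[k, 2L]
      } else {
        keep[[length(keep) + 1L]] <- ints[k, ]
      }
    }
    ints <- do.call(rbind, keep)
  }
  recording(data, fs, seizure_intervals = ints)
}
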