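#' Specification of a synthetic motor-imagery EEG recording
#'
#' Bundles and validates the parameters of the event-related
#' desynchronization/synchronization (ERD/ERS) simulator. The simulated
#' paradigm mirrors a cue-based upper-limb motor-imagery session on a
#' three-channel sensorimotor montage (C3, Cz, C4) sampled at 250 Hz:
#' 8-second trials in randomized order, imagery modulating the mu
#' (8--12 Hz) and beta rhythms inside `mi_window`, contralateral power
#' suppressed (ERD) and ipsilateral power enhanced (ERS).
#'
#' Class labels are positional: with 2 classes the first is left-limb
#' imagery and the second rest; with 3 classes they are left-limb imagery,
#' right-limb imagery, rest. The rest class is never modulated.
#'
#' @param n_trials_per_class trials per class (>= 1).
#' @param classes character vector of 2 or 3 distinct labels (see Details).
#' @param sampling_rate sampling rate in Hz.
#' @param channels three channel names ordered left hemisphere, midline,
#'   right hemisphere.
#' @param trial_duration trial length in seconds.
#' @param mi_window two-element numeric, seconds relative to trial onset in
#'   which rhythm power is modulated.
#' @param erd_depth fraction in `[0, 1)`: contralateral mu/beta power is
#'   multiplied by `1 - erd_depth`.
#' @param ers_gain fraction `>= 0`: ipsilateral power multiplied by
#'   `1 + ers_gain`.
#' @param noise_exponent spectral slope of the 1/f^a background noise.
#' @param rhythm_amplitudes named numeric `c(mu = ..., beta = ...)`, RMS
#'   amplitudes in microvolts of the two band-limited rhythm processes.
#' @param noise_amplitude RMS amplitude in microvolts of the broadband
#'   background noise.
#' @param artifact_rate probability per trial of injecting a high-amplitude
#'   transient.
#' @param artifact_amplitude peak amplitude in microvolts of injected
#'   artifacts.
#' @param seed integer RNG seed; the full recording is a deterministic
#'   function of the spec.
#' @return an object of class `sim_spec`.
#' @seealso [generate_recording()]
#' @export
sim_spec <- function(n_trials_per_class = 100,
                     classes = c("left", "relax"),
                     sampling_rate = 250,
                     channels = c("C3", "Cz", "C4"),
                     trial_duration = 8,
                     mi_window = c(3.5, 5.5),
                     erd_depth = 0.5,
                     ers_gain = 2.5,
                     noise_exponent = 1,
                     rhythm_amplitudes = c(mu = 9, beta = 5),
                     noise_amplitude = 7,
                     artifact_rate = 0,
                     artifact_amplitude = 150,
                     seed = 1) {
  .assert(is.numeric(n_trials_per_class) && n_trials_per_class >= 1,
          "invalid 'n_trials_per_class': must be >= 1")
  .assert(length(classes) %in% c(2L, 3L) && !anyDuplicated(classes),
          "invalid 'classes': need 2 or 3 distinct labels")
  .assert(is.numeric(sampling_rate) && sampling_rate > 0,
          "invalid 'sampling_rate': must be positive")
  .assert(length(channels) == 3L && !anyDuplicated(channels),
          "invalid 'channels': need 3 unique names")
  .assert(is.numeric(trial_duration) && trial_duration > 0,
          "invalid 'trial_duration': must be positive")
  .assert(length(mi_window) == 2L && mi_window[1] < mi_window[2] &&
            mi_window[1] >= 0 && mi_window[2] <= trial_duration,
          "invalid 'mi_window': must lie inside the trial")
  .assert(is.numeric(erd_depth) && erd_depth >= 0 && erd_depth < 1,
          "invalid 'erd_depth': must be in [0, 1)")
  .assert(is.numeric(ers_gain) && ers_gain >= 0,
          "invalid 'ers_gain': must be >= 0")
  .assert(is.numeric(rhythm_amplitudes) && length(rhythm_amplitudes) == 2L &&
            all(rhythm_amplitudes >= 0),
          "invalid 'rhythm_amplitudes': need nonnegative c(mu, beta)")
  .assert(is.numeric(noise_amplitude) && noise_amplitude >= 0,
          "invalid 'noise_amplitude': must be >= 0")
  .assert(is.numeric(artifact_rate) && artifact_rate >= 0 && artifact_rate <= 1,
          "invalid 'artifact_rate': must be in [0, 1]")
  spec <- list(n_trials_per_class = as.integer(n_trials_per_class),
               classes = as.character(classes),
               sampling_rate = sampling_rate,
               channels = as.character(channels),
               trial_duration = trial_duration,
               mi_window = as.numeric(mi_window),
               erd_depth = erd_depth,
               ers_gain = ers_gain,
               noise_exponent = noise_exponent,
               rhythm_amplitudes = unname(rhythm_amplitudes),
               noise_amplitude = noise_amplitude,
               artifact_rate = artifact_rate,
               artifact_amplitude = artifact_amplitude,
               seed = as.integer(seed))
  class(spec) <- "sim_spec"
  spec
}

#' @export
print.sim_spec <- function(x, ...) {
  cat("Synthetic MI-EEG spec:", length(x$classes), "classes (",
      paste(x$classes, collapse = ", "), "), ",
      x$n_trials_per_class, "trials/class @", x$sampling_rate, "Hz\n")
  cat("  ERD depth", x$erd_depth, "| ERS gain", x$ers_gain,
      "| modulation window", x$mi_window[1], "-", x$mi_window[2], "s\n")
  invisible(x)
}

# continuous 1/f^a Gaussian noise via spectral shaping, unit variance;
# generated at a highly composite length (fast FFT) and truncated
.pink_noise <- function(n, exponent) {
  if (exponent == 0) return(stats::rnorm(n))
  nf <- stats::nextn(n)
  white <- stats::rnorm(nf)
  spec <- stats::fft(white)
  k <- seq_len(nf) - 1L
  k <- pmin(k, nf - k)             # two-sided frequency index
  shape <- c(0, k[-1]^(-exponent / 2))
  x <- Re(stats::fft(spec * shape, inverse = TRUE))[seq_len(n)] / nf
  x / stats::sd(x)
}

# band-limited Gaussian rhythm process, unit variance; an 8th-order
# design keeps the rhythm spectrally confined to its nominal band so
# class modulation does not bleed into neighbouring analysis sub-bands
.rhythm_noise <- function(n, band, sampling_rate) {
  filt <- .bp_design(band[1], band[2], sampling_rate, 8)
  x <- signal::filtfilt(filt, stats::rnorm(n))
  x / stats::sd(x)
}

# per-class power gains for (left-hemisphere, midline, right-hemisphere)
# channels; the midline carries a strongly attenuated mixture
.class_gains <- function(label_index, n_classes, erd_depth, ers_gain) {
  cz <- (1 - 0.25 * erd_depth) * (1 + 0.25 * ers_gain)
  if (n_classes == 2L) {
    # 1 = left-limb imagery (contralateral = right hemisphere), 2 = rest
    if (label_index == 1L) c(1 + ers_gain, cz, 1 - erd_depth) else c(1, 1, 1)
  } else {
    switch(label_index,
           c(1 + ers_gain, cz, 1 - erd_depth),  # left-limb imagery
           c(1 - erd_depth, cz, 1 + ers_gain),  # right-limb imagery
           c(1, 1, 1))                          # rest
  }
}

# write the amplitude envelope of one trial's modulation into `env`
# in place: 1 outside the window, sqrt(gain) inside, raised-cosine
# ramped over `ramp_s` seconds at both edges
.apply_envelope <- function(env, onset, win, gain, sampling_rate,
                            ramp_s = 0.25) {
  if (gain == 1) return(env)
  a <- sqrt(gain)
  i0 <- onset + round(win[1] * sampling_rate)
  i1 <- onset + round(win[2] * sampling_rate) - 1L
  nr <- max(1L, round(ramp_s * sampling_rate))
  ramp <- (1 - cos(pi * seq_len(nr) / nr)) / 2   # 0 -> 1
  env[i0:i1] <- a
  env[i0:(i0 + nr - 1L)] <- 1 + (a - 1) * ramp
  env[(i1 - nr + 1L):i1] <- a + (1 - a) * ramp
  env
}

#' Generate a continuous synthetic motor-imagery EEG recording
#'
#' Builds one continuous multichannel recording containing
#' `n_trials_per_class * length(classes)` trials in randomized order with
#' random inter-trial rest gaps (uniform 1.5--3.5 s). Each channel is the
#' sum of 1/f background noise and two band-limited rhythm processes
#' (mu 8--12 Hz, beta 16--24 Hz core) whose power is modulated inside each
#' trial's `mi_window` according to the trial's class: contralateral power
#' times `1 - erd_depth` (ERD), ipsilateral times `1 + ers_gain` (ERS),
#' midline a strongly attenuated mixture, rest class unmodulated.
#' Rhythms are narrow-band filtered noise rather than sinusoids so that
#' spatial covariance matrices have full rank.
#'
#' @param spec a [sim_spec()] object.
#' @return a list with components `recording` (a `raw_recording`: matrix
#'   `data` channels x samples in microvolts, `sampling_rate`,
#'   `channel_names`, `events` data frame of onset samples and labels) and
#'   `labels` (factor, one per trial in recording order).
#' @export
generate_recording <- function(spec) {
  .assert(inherits(spec, "sim_spec"), "invalid 'spec': not a sim_spec object")
  fs <- spec$sampling_rate
  n_classes <- length(spec$classes)
  n_trials <- spec$n_trials_per_class * n_classes
  trial_len <- round(spec$trial_duration * fs)

  with_seed(spec$seed, {
    order_idx <- sample(rep(seq_len(n_classes), spec$n_trials_per_class))
    gaps <- stats::runif(n_trials, 1.5, 3.5)

    onsets <- integer(n_trials)
    pos <- round(2 * fs)                       # 2-s lead-in
    for (i in seq_len(n_trials)) {
      pos <- pos + round(gaps[i] * fs)
      onsets[i] <- as.integer(pos + 1)         # 1-based onset sample
      pos <- pos + trial_len
    }
    n <- pos + round(fs)                       # 1-s tail

    data <- matrix(0, nrow = 3L, ncol = n,
                   dimnames = list(spec$channels, NULL))
    amp <- spec$rhythm_amplitudes
    bands <- list(mu = c(8, 12), beta = c(16, 24))
    for (ch in 1:3) {
      sig <- spec$noise_amplitude * .pink_noise(n, spec$noise_exponent)
      for (b in 1:2) {
        if (amp[b] <= 0) next
        rhythm <- amp[b] * .rhythm_noise(n, bands[[b]], fs)
        env <- rep(1, n)
        for (i in seq_len(n_trials)) {
          g <- .class_gains(order_idx[i], n_classes,
                            spec$erd_depth, spec$ers_gain)[ch]
          env <- .apply_envelope(env, onsets[i], spec$mi_window, g, fs)
        }
        sig <- sig + rhythm * env
      }
      data[ch, ] <- sig
    }

    labels <- factor(spec$classes[order_idx], levels = spec$classes)
    rec <- structure(list(data = data,
                          sampling_rate = fs,
                          channel_names = spec$channels,
                          events = data.frame(onset = onsets,
                                              label = as.character(labels),
                                              stringsAsFactors = FALSE),
                          trial_duration = spec$trial_duration),
                     class = "raw_recording")
    if (spec$artifact_rate > 0) {
      hit <- stats::runif(n_trials) < spec$artifact_rate
      for (i in which(hit))
        rec <- inject_artifact(rec, i, spec$artifact_amplitude)
    }
    list(recording = rec, labels = labels)
  })
}

#' @export
print.raw_recording <- function(x, ...) {
  cat("raw_recording:", nrow(x$data), "channels x", ncol(x$data),
      "samples @", x$sampling_rate, "Hz,", nrow(x$events), "events\n")
  invisible(x)
}

#' Inject a high-amplitude transient artifact into one trial
#'
#' Adds a 0.4-s raised-cosine pulse on the first channel, centred 3 s after
#' the trial's onset (inside the standard 1--5 s decoding epoch), scaled so
#' that the peak sample equals `peak_amplitude` exactly. Used to construct
#' fixtures for amplitude-based trial rejection. `peak_amplitude = 0`
#' returns the recording unchanged.
#'
#' @param recording a `raw_recording`.
#' @param trial_index event index to corrupt.
#' @param peak_amplitude target peak value in microvolts.
#' @param channel channel index carrying the transient.
#' @return the modified `raw_recording`.
#' @export
inject_artifact <- function(recording, trial_index, peak_amplitude,
                            channel = 1L) {
  .assert(inherits(recording, "raw_recording"), "not a raw_recording")
  n_ev <- nrow(recording$events)
  .assert(trial_index >= 1 && trial_index <= n_ev,
          "trial_index %s out of range 1..%d", trial_index, n_ev)
  if (peak_amplitude == 0) return(recording)
  fs <- recording$sampling_rate
  onset <- recording$events$onset[trial_index]
  centre <- onset + round(3 * fs)
  half <- round(0.2 * fs)
  idx <- (centre - half):(centre + half)
  idx <- idx[idx >= 1 & idx <= ncol(recording$data)]
  pulse <- (1 + cos(pi * (idx - centre) / half)) / 2   # 1 at centre
  base <- recording$data[channel, centre]
  recording$data[channel, idx] <-
    recording$data[channel, idx] + (peak_amplitude - base) * pulse
  recording
}
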