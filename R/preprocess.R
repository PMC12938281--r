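#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass of the stated design order forward and
#' backward (zero net phase; effective magnitude response of twice the
#' design order). Signals are padded by 0.5 s of odd reflection on each
#' side before filtering and cropped afterwards, which suppresses the edge
#' transients of forward--backward filtering on short epochs. The front-end
#' default is the 4--40 Hz, 8th-order design used ahead of spatial
#' filtering.
#'
#' @param x numeric vector, channels x samples matrix, or `epoch_set`.
#' @param low_hz,high_hz band edges in Hz; must satisfy
#'   `0 < low < high < sampling_rate / 2`.
#' @param sampling_rate sampling rate in Hz (taken from `x` when `x` is an
#'   `epoch_set`).
#' @param order overall band-pass design order (even).
#' @param pad_s reflection padding in seconds.
#' @return filtered object of the same shape/class as `x`.
#' @export
bandpass_zero_phase <- function(x, low_hz = 4, high_hz = 40,
                                sampling_rate = NULL, order = 8,
                                pad_s = 0.5) {
  if (inherits(x, "epoch_set")) {
    filt <- .bp_design(low_hz, high_hz, x$sampling_rate, order)
    pad <- round(pad_s * x$sampling_rate)
    out <- x
    for (i in seq_len(n_trials(x)))
      out$data[i, , ] <- .bp_matrix(.trial(x, i), filt, pad)
    return(out)
  }
  .assert(!is.null(sampling_rate), "'sampling_rate' is required")
  filt <- .bp_design(low_hz, high_hz, sampling_rate, order)
  pad <- round(pad_s * sampling_rate)
  if (is.matrix(x)) .bp_matrix(x, filt, pad)
  else .filtfilt_padded(filt, x, pad)
}

#' Extract fixed-length epochs around event onsets
#'
#' Cuts one epoch per event over the half-open window
#' `[start_s, end_s)` in seconds relative to the event onset (sample
#' values are copied verbatim; no resampling). At 250 Hz the default
#' 1--5 s imagery window yields 1000-sample epochs. Events whose window
#' would run past the end of the recording are dropped with a warning.
#'
#' @param recording a `raw_recording`.
#' @param start_s,end_s epoch window in seconds relative to onset.
#' @return an `epoch_set` labelled from the event markers.
#' @export
epoch_recording <- function(recording, start_s = 1, end_s = 5) {
  .assert(inherits(recording, "raw_recording"), "not a raw_recording")
  .assert(end_s > start_s, "empty epoch window [%g, %g)", start_s, end_s)
  fs <- recording$sampling_rate
  n <- ncol(recording$data)
  i0 <- round(start_s * fs)
  i1 <- round(end_s * fs) - 1L
  len <- i1 - i0 + 1L
  keep <- logical(nrow(recording$events))
  for (i in seq_along(keep)) {
    onset <- recording$events$onset[i]
    if (onset + i1 <= n && onset + i0 >= 1) keep[i] <- TRUE
    else warning(sprintf("dropping trial %d: window exceeds recording", i),
                 call. = FALSE)
  }
  .assert(any(keep), "no epochs could be extracted")
  ev <- recording$events[keep, , drop = FALSE]
  arr <- array(NA_real_, c(nrow(ev), nrow(recording$data), len))
  for (i in seq_len(nrow(ev)))
    arr[i, , ] <- recording$data[, (ev$onset[i] + i0):(ev$onset[i] + i1)]
  epoch_set(arr, ev$label, fs, recording$channel_names,
            window = c(start_s, end_s))
}

#' Reject trials exceeding an amplitude threshold
#'
#' Removes trials in which any channel's absolute amplitude exceeds
#' `threshold_uv` (the +/- 100 microvolt envelope rule: equivalently a
#' peak-to-peak excursion above twice the threshold for symmetric
#' signals). Surviving trials keep their original order.
#'
#' @param epochs an `epoch_set`.
#' @param threshold_uv rejection threshold in microvolts (> 0).
#' @return the cleaned `epoch_set`, with a `rejection` attribute: a data
#'   frame of removed trial indices, the first offending channel, and the
#'   peak absolute amplitude.
#' @export
reject_artifacts <- function(epochs, threshold_uv = 100) {
  .assert(inherits(epochs, "epoch_set"), "not an epoch_set")
  .assert(threshold_uv > 0, "'threshold_uv' must be positive")
  nt <- n_trials(epochs)
  bad <- integer(0); ch <- character(0); peak <- numeric(0)
  for (i in seq_len(nt)) {
    m <- abs(.trial(epochs, i))
    pk <- apply(m, 1, max)
    if (any(pk > threshold_uv)) {
      j <- which(pk > threshold_uv)[1]
      bad <- c(bad, i)
      ch <- c(ch, epochs$channel_names[j])
      peak <- c(peak, max(pk))
    }
  }
  .assert(length(bad) < nt,
          "all %d trials exceed %g microvolts; review the threshold",
          nt, threshold_uv)
  keep <- setdiff(seq_len(nt), bad)
  out <- .subset_epochs(epochs, keep)
  attr(out, "rejection") <- data.frame(index = bad, channel = ch,
                                       peak = peak,
                                       stringsAsFactors = FALSE)
  out
}
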