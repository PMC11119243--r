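#' Cue-relative epoch window
#'
#' Describes the analysis segment relative to each cue marker, in seconds.
#' Sample windows are half-open `[start, end)` so that a window of duration
#' `d` at sampling rate `fs` yields exactly `round(d * fs)` samples: a 4-s
#' window at 100 Hz gives 400 samples, a `[0.5, 3)` s window gives 250.
#'
#' @param start_offset_s window start relative to the cue, seconds.
#' @param end_offset_s window end relative to the cue, seconds
#'   (must exceed `start_offset_s`).
#' @return an `epoch_window` object.
#' @export
epoch_window <- function(start_offset_s, end_offset_s) {
  if (!is.numeric(start_offset_s) || !is.numeric(end_offset_s) ||
      length(start_offset_s) != 1L || length(end_offset_s) != 1L)
    stopf("epoch_window: offsets must be numeric scalars")
  if (end_offset_s <= start_offset_s)
    stopf("epoch_window: end offset (%g) must exceed start offset (%g)",
          end_offset_s, start_offset_s)
  structure(list(start_offset_s = start_offset_s, end_offset_s = end_offset_s),
            class = "epoch_window")
}

#' Bandpass filter specification
#'
#' @param low_hz,high_hz band edges in Hz, `0 < low < high`.
#' @param order Butterworth order (default 5).
#' @param zero_phase apply forwards and backwards (zero group delay)? Default
#'   `TRUE`; the effective magnitude response is then the square of the
#'   single-pass response.
#' @return a `bandpass_spec` object.
#' @export
bandpass_spec <- function(low_hz = 8, high_hz = 35, order = 5L,
                          zero_phase = TRUE) {
  if (!(low_hz > 0 && high_hz > low_hz))
    stopf("bandpass_spec: need 0 < low_hz < high_hz")
  order <- as.integer(order)
  if (order < 1L) stopf("bandpass_spec: order must be >= 1")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = order,
                 zero_phase = isTRUE(zero_phase)),
            class = "bandpass_spec")
}

#' Extract cue-aligned trials from a continuous recording
#'
#' Cuts one trial per *labeled* event (label 1 or 2); events with unknown
#' label are skipped. Trial `m`, sample `n` (0-based) equals the continuous
#' sample at `event_m + round(start * fs) + n`.
#'
#' @param continuous a [continuous_eeg()] recording.
#' @param window an [epoch_window()]; e.g. `epoch_window(0.5, 3)` for a
#'   0.5--3 s post-cue imagery segment or `epoch_window(0, 4)` for a full
#'   4-s cue window.
#' @return an [epoched_eeg()] with `N = round((end - start) * fs)` samples
#'   per trial.
#' @export
epoch_trials <- function(continuous, window) {
  stopifnot(inherits(continuous, "continuous_eeg"),
            inherits(window, "epoch_window"))
  fs <- continuous$fs
  T_len <- ncol(continuous$data)
  ev <- continuous$events
  ev <- ev[!is.na(ev$label), , drop = FALSE]
  if (nrow(ev) == 0L)
    stopf("epoch_trials: recording has no labeled events")
  start_samp <- as.integer(round(window$start_offset_s * fs))
  n_samp <- as.integer(round((window$end_offset_s - window$start_offset_s) * fs))
  if (n_samp < 2L) stopf("epoch_trials: window too short (%d samples)", n_samp)
  M <- nrow(ev); L <- nrow(continuous$data)
  out <- array(0, dim = c(M, L, n_samp))
  for (m in seq_len(M)) {
    first <- ev$sample[m] + start_samp        # 0-based
    last <- first + n_samp - 1L
    if (first < 0L || last >= T_len)
      stopf("epoch_trials: window [%d, %d] for event %d falls outside the recording (0..%d)",
            first, last, m, T_len - 1L)
    out[m, , ] <- continuous$data[, (first + 1L):(last + 1L)]
  }
  epoched_eeg(out, fs = fs, channel_names = continuous$channel_names,
              labels = ev$label)
}

#' Bandpass-filter every trial and channel
#'
#' Butterworth bandpass applied along the sample axis of each trial/channel.
#' The default is the broadband 8--35 Hz fifth-order zero-phase stage that
#' precedes channel scoring and sub-band decomposition.
#'
#' @param epoched an [epoched_eeg()].
#' @param spec a [bandpass_spec()]; band edges must satisfy
#'   `high_hz < fs / 2`.
#' @return an [epoched_eeg()] of the same shape.
#' @export
eeg_bandpass <- function(epoched, spec = bandpass_spec()) {
  stopifnot(inherits(epoched, "epoched_eeg"), inherits(spec, "bandpass_spec"))
  ba <- butter_bandpass(spec$low_hz, spec$high_hz, epoched$fs, spec$order)
  out <- filter_tensor(epoched$data, ba$b, ba$a, zero_phase = spec$zero_phase)
  epoched_eeg(out, fs = epoched$fs, channel_names = epoched$channel_names,
              labels = epoched$labels)
}
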