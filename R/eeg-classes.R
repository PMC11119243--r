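#' Continuous multichannel EEG recording
#'
#' Container for an unsegmented EEG recording: a channels-by-samples matrix
#' (microvolts), its sampling rate, channel names, and cue/event markers.
#' Validation happens at construction so that malformed inputs are rejected
#' before they reach any pipeline stage.
#'
#' @param data numeric matrix, L channels x T samples.
#' @param fs sampling rate in Hz (positive scalar).
#' @param channel_names character vector of length L; defaults to
#'   `"ch1" ... "chL"`. Must be unique.
#' @param events data frame with columns `sample` (0-based sample index of the
#'   cue) and `label` (class id `1`, `2`, or `NA` for unknown). May be `NULL`
#'   for an event-free recording.
#' @return an object of class `continuous_eeg`.
#' @seealso [epoched_eeg()], [epoch_trials()]
#' @export
continuous_eeg <- function(data, fs, channel_names = NULL, events = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data) || anyNA(data) || any(!is.finite(data)))
    stopf("continuous_eeg: data must be a finite numeric matrix")
  L <- nrow(data); T_len <- ncol(data)
  if (L < 1L || T_len < 2L)
    stopf("continuous_eeg: need at least 1 channel and 2 samples, got %d x %d", L, T_len)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stopf("continuous_eeg: fs must be a positive scalar (Hz)")
  channel_names <- channel_names %||% paste0("ch", seq_len(L))
  channel_names <- as.character(channel_names)
  if (length(channel_names) != L)
    stopf("continuous_eeg: %d channel names for %d channels", length(channel_names), L)
  if (anyDuplicated(channel_names))
    stopf("continuous_eeg: channel names must be unique")
  if (is.null(events)) {
    events <- data.frame(sample = integer(0), label = integer(0))
  } else {
    events <- as.data.frame(events)
    if (!all(c("sample", "label") %in% names(events)))
      stopf("continuous_eeg: events need columns 'sample' and 'label'")
    events$sample <- as.integer(events$sample)
    events$label <- suppressWarnings(as.integer(events$label))
    if (any(events$sample < 0L) || any(events$sample >= T_len))
      stopf("continuous_eeg: event sample indices must lie in [0, %d)", T_len)
    bad <- !is.na(events$label) & !(events$label %in% c(1L, 2L))
    if (any(bad))
      stopf("continuous_eeg: event labels must be 1, 2 or NA")
  }
  rownames(data) <- channel_names
  structure(
    list(data = data, fs = as.numeric(fs), channel_names = channel_names,
         events = events),
    class = "continuous_eeg")
}

#' Epoched (trial-segmented) EEG
#'
#' Container for cue-aligned trials: an M trials x L channels x N samples
#' array (microvolts) with one class label per trial. Two-class convention:
#' labels take values in `{1, 2}` and class 1 is the positive class
#' throughout the package.
#'
#' @param data numeric array, M x L x N.
#' @param fs sampling rate in Hz.
#' @param channel_names character vector of length L (unique); defaults to
#'   `"ch1" ... "chL"`.
#' @param labels integer vector of length M with values in `{1, 2}`.
#' @return an object of class `epoched_eeg`.
#' @seealso [continuous_eeg()], [channel_entropy()], [apply_filterbank()]
#' @export
epoched_eeg <- function(data, fs, channel_names = NULL, labels) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("epoched_eeg: data must be an M x L x N array")
  if (!is.numeric(data) || anyNA(data) || any(!is.finite(data)))
    stopf("epoched_eeg: data must be finite numeric")
  d <- dim(data)
  if (d[1] < 1L || d[2] < 1L || d[3] < 2L)
    stopf("epoched_eeg: need M >= 1, L >= 1, N >= 2; got %d x %d x %d",
          d[1], d[2], d[3])
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stopf("epoched_eeg: fs must be a positive scalar (Hz)")
  channel_names <- channel_names %||% paste0("ch", seq_len(d[2]))
  channel_names <- as.character(channel_names)
  if (length(channel_names) != d[2])
    stopf("epoched_eeg: %d channel names for %d channels",
          length(channel_names), d[2])
  if (anyDuplicated(channel_names))
    stopf("epoched_eeg: channel names must be unique")
  labels <- as.integer(labels)
  if (length(labels) != d[1])
    stopf("epoched_eeg: %d labels for %d trials", length(labels), d[1])
  if (anyNA(labels) || !all(labels %in% c(1L, 2L)))
    stopf("epoched_eeg: labels must be 1 or 2")
  structure(
    list(data = data, fs = as.numeric(fs), channel_names = channel_names,
         labels = labels),
    class = "epoched_eeg")
}

#' @export
print.continuous_eeg <- function(x, ...) {
  cat(sprintf("<continuous_eeg> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              nrow(x$events)))
  invisible(x)
}

#' @export
print.epoched_eeg <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoched_eeg> %d trials x %d channels x %d samples @ %g Hz; class counts: %s\n",
              d[1], d[2], d[3], x$fs,
              paste(sprintf("%d:%d", 1:2, tabulate(x$labels, 2L)), collapse = " ")))
  invisible(x)
}

#' Dimensions of an epoched EEG object
#' @param x an `epoched_eeg`.
#' @return integer vector `c(M, L, N)`.
#' @export
dim.epoched_eeg <- function(x) dim(x$data)

# Number of trials per class; errors unless both classes are present.
check_two_classes <- function(epoched) {
  tab <- tabulate(epoched$labels, 2L)
  if (any(tab == 0L))
    stopf("both classes must be present (class counts: %d, %d)", tab[1], tab[2])
  tab
}
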