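#' Default motor-imagery sub-bands
#'
#' Mu (8--13 Hz), low beta (13--22 Hz), high beta (22--35 Hz) and the full
#' 8--35 Hz band. The bands share edges and the full band deliberately
#' duplicates the narrow bands' content; the CSP stage extracts different
#' spatial structure from each.
#'
#' @return list of `c(low, high)` pairs in Hz.
#' @export
default_bands <- function() {
  list(c(8, 13), c(13, 22), c(22, 35), c(8, 35))
}

#' Filter-bank specification
#'
#' @param bands ordered list of `c(low_hz, high_hz)` pairs; default
#'   [default_bands()].
#' @param order Butterworth order per band (default 5, the same order as the
#'   broadband stage).
#' @return a `filterbank_spec` object.
#' @export
filterbank_spec <- function(bands = default_bands(), order = 5L) {
  if (!is.list(bands) || length(bands) < 1L)
    stopf("filterbank_spec: bands must be a nonempty list of c(low, high)")
  for (b in bands) {
    if (length(b) != 2L || !is.numeric(b) || !(b[1] > 0 && b[2] > b[1]))
      stopf("filterbank_spec: each band must satisfy 0 < low < high")
  }
  structure(list(bands = lapply(bands, as.numeric), order = as.integer(order)),
            class = "filterbank_spec")
}

#' Decompose trials into sub-bands
#'
#' Applies one zero-phase Butterworth bandpass per band to every trial and
#' channel, stacking the results into an S x M x L x N tensor. Each band
#' layer equals [eeg_bandpass()] with that band's [bandpass_spec()]; the
#' filter bank simply reuses that engine per band.
#'
#' @param epoched an [epoched_eeg()] (typically after channel selection).
#' @param spec a [filterbank_spec()]; every band must satisfy
#'   `high < fs / 2`.
#' @return a `subband_eeg` object: `data` (S x M x L x N array), `spec`,
#'   plus `fs`, `labels`, `channel_names` carried over.
#' @export
apply_filterbank <- function(epoched, spec = filterbank_spec()) {
  stopifnot(inherits(epoched, "epoched_eeg"), inherits(spec, "filterbank_spec"))
  d <- dim(epoched$data)
  S <- length(spec$bands)
  out <- array(0, dim = c(S, d[1], d[2], d[3]))
  for (s in seq_len(S)) {
    band <- spec$bands[[s]]
    ba <- tryCatch(
      butter_bandpass(band[1], band[2], epoched$fs, spec$order),
      error = function(e) stopf("filter bank band %d [%g, %g] Hz: %s",
                                s, band[1], band[2], conditionMessage(e)))
    out[s, , , ] <- filter_tensor(epoched$data, ba$b, ba$a, zero_phase = TRUE)
  }
  structure(
    list(data = out, spec = spec, fs = epoched$fs, labels = epoched$labels,
         channel_names = epoched$channel_names),
    class = "subband_eeg")
}

#' @export
print.subband_eeg <- function(x, ...) {
  d <- dim(x$data)
  bands <- vapply(x$spec$bands, function(b) sprintf("%g-%g", b[1], b[2]), "")
  cat(sprintf("<subband_eeg> %d bands (%s Hz) x %d trials x %d channels x %d samples\n",
              d[1], paste(bands, collapse = ", "), d[2], d[3], d[4]))
  invisible(x)
}
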