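# Zero-phase IIR filtering engine.
#
# Design is delegated to signal::butter(); application uses a compiled
# direct-form II transposed filter with steady-state initial conditions and
# odd-extension padding, so the forward-backward pass has zero group delay
# and no start-up transient. The effective magnitude response is the square
# of the single-pass response.

# Pad b and a to equal length and normalize so a[1] == 1.
normalize_ba <- function(b, a) {
  n <- max(length(b), length(a))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  if (a[1] == 0) stopf("filter: a[1] must be nonzero")
  list(b = b / a[1], a = a / a[1], n = n)
}

# Steady-state initial filter state for a unit-step input: the state that
# makes the filter output immediately equal its DC-consistent response,
# eliminating the start-up transient (companion-matrix linear solve).
lfilter_zi <- function(b, a) {
  ba <- normalize_ba(b, a)
  n <- ba$n
  if (n == 1L) return(numeric(0))
  A <- matrix(0, n - 1L, n - 1L)
  A[1L, ] <- -ba$a[2:n]
  if (n > 2L) A[cbind(2:(n - 1L), 1:(n - 2L))] <- 1
  B <- ba$b[2:n] - ba$a[2:n] * ba$b[1]
  solve(diag(n - 1L) - t(A), B)
}

# Single-pass IIR filter, optional initial state.
lfilter <- function(b, a, x, zi = NULL) {
  ba <- normalize_ba(b, a)
  if (is.null(zi)) zi <- rep(0, ba$n - 1L)
  lfilter_cpp(ba$b, ba$a, as.numeric(x), as.numeric(zi))
}

#' Zero-phase (forward-backward) IIR filtering
#'
#' Applies the filter `(b, a)` forwards and backwards so the net group delay
#' is zero. The signal is extended at both ends by odd reflection of length
#' `padlen` (default three times the filter state dimension) and each pass is
#' started from its steady state relative to the first padded sample.
#'
#' @param b,a filter numerator/denominator coefficients.
#' @param x numeric signal.
#' @param padlen edge padding length in samples; `x` must be longer than
#'   `padlen`.
#' @return filtered signal, same length as `x`.
#' @keywords internal
filtfilt_ba <- function(b, a, x, padlen = NULL) {
  ba <- normalize_ba(b, a)
  padlen <- padlen %||% (3L * (ba$n - 1L))
  nx <- length(x)
  if (nx <= padlen)
    stopf("zero-phase filter: signal length %d must exceed padding %d", nx, padlen)
  if (padlen > 0L) {
    pre <- 2 * x[1] - x[(padlen + 1L):2L]
    post <- 2 * x[nx] - x[(nx - 1L):(nx - padlen)]
    ext <- c(pre, x, post)
  } else ext <- x
  zi <- lfilter_zi(ba$b, ba$a)
  y <- lfilter_cpp(ba$b, ba$a, ext, zi * ext[1])
  y <- rev(lfilter_cpp(ba$b, ba$a, rev(y), zi * y[length(y)]))
  y[(padlen + 1L):(padlen + nx)]
}

# Butterworth bandpass design for a given sampling rate. Returns b, a.
butter_bandpass <- function(low_hz, high_hz, fs, order) {
  nyq <- fs / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stopf("band [%g, %g] Hz invalid for fs = %g Hz (need 0 < low < high < %g)",
          low_hz, high_hz, fs, nyq)
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  list(b = as.numeric(bf$b), a = as.numeric(bf$a))
}

# Filter one trial tensor (M x L x N) along the sample axis.
filter_tensor <- function(data, b, a, zero_phase = TRUE) {
  d <- dim(data)
  out <- data
  for (m in seq_len(d[1])) {
    for (l in seq_len(d[2])) {
      x <- data[m, l, ]
      out[m, l, ] <- if (zero_phase) filtfilt_ba(b, a, x) else lfilter(b, a, x)
    }
  }
  out
}
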