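# Shared fixture builders. Everything is generated in code under fixed
# seeds; nothing is read from disk.

# Small random epoched dataset with both classes present.
random_epoched <- function(M = 4L, L = 3L, N = 12L, fs = 100, seed = 1L) {
  set.seed(seed)
  labels <- rep_len(1:2, M)
  epoched_eeg(array(rnorm(M * L * N), dim = c(M, L, N)), fs = fs,
              labels = labels)
}

# Continuous recording with labeled events placed away from the edges.
random_continuous <- function(L = 3L, T_len = 3000L, fs = 100,
                              n_events = 6L, seed = 1L) {
  set.seed(seed)
  ev_at <- as.integer(seq(200L, T_len - 600L, length.out = n_events))
  continuous_eeg(matrix(rnorm(L * T_len), L, T_len), fs = fs,
                 events = data.frame(sample = ev_at,
                                     label = rep_len(1:2, n_events)))
}

# Pure sinusoid trial tensor (1 trial, 1 channel).
sine_epoched <- function(freq, fs = 100, dur_s = 4, amp = 1) {
  tt <- (0:(dur_s * fs - 1)) / fs
  x <- amp * sin(2 * pi * freq * tt)
  arr <- array(0, dim = c(2L, 1L, length(x)))
  arr[1, 1, ] <- x
  arr[2, 1, ] <- x
  epoched_eeg(arr, fs = fs, labels = 1:2)
}

# Independent histogram-entropy oracle: explicit per-bin counting loop,
# sharing no code with trial_entropy().
oracle_entropy <- function(x, bins) {
  lo <- min(x); hi <- max(x)
  if (lo == hi) return(0)
  edges <- seq(lo, hi, length.out = bins + 1L)
  h <- 0
  for (b in seq_len(bins)) {
    inside <- if (b < bins) sum(x >= edges[b] & x < edges[b + 1L])
              else sum(x >= edges[b] & x <= edges[b + 1L])
    if (inside > 0) {
      p <- inside / length(x)
      h <- h - p * log(p)
    }
  }
  h
}

# Brute-force class covariance oracle with explicit loops.
oracle_class_cov <- function(trials, labels, class) {
  idx <- which(labels == class)
  L <- dim(trials)[2]
  acc <- matrix(0, L, L)
  for (m in idx) {
    X <- matrix(trials[m, , ], nrow = L)
    C <- matrix(0, L, L)
    for (i in seq_len(L)) for (j in seq_len(L))
      C[i, j] <- sum(X[i, ] * X[j, ])
    acc <- acc + C / sum(diag(C))
  }
  acc / length(idx)
}

# Random symmetric positive-definite matrix.
random_spd <- function(L, seed) {
  set.seed(seed)
  A <- matrix(rnorm(L * L), L, L)
  crossprod(A) + 0.1 * diag(L)
}
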