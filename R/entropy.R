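#' Shannon entropy of one trial's amplitude distribution
#'
#' Amplitudes are binned into `bins` equal-width cells spanning
#' `[min(x), max(x)]`; the entropy is `-sum(p * log(p))` over occupied bins,
#' in nats. Because the bin edges scale with the data range, the score is
#' invariant to affine rescaling of the signal; it measures the *shape* of
#' the amplitude distribution, not its magnitude. A constant signal occupies
#' a single bin and scores 0; the maximum is `log(bins)` at exactly uniform
#' occupancy.
#'
#' @param x numeric sample vector, length >= 2, finite.
#' @param bins number of histogram bins (default 256).
#' @param variant `"shannon"` (default) computes the usual
#'   `-sum(p_b log p_b)` over bin probabilities. `"per_sample"` instead sums
#'   `-p(x(n)) log p(x(n))` over samples and is provided for comparison with
#'   formulations that weight each bin by its occupancy count; it is not a
#'   Shannon entropy and is never used downstream by default.
#' @return entropy in nats (nonnegative scalar).
#' @export
trial_entropy <- function(x, bins = 256L, variant = c("shannon", "per_sample")) {
  variant <- match.arg(variant)
  x <- as.numeric(x)
  if (length(x) < 2L) stopf("trial_entropy: need at least 2 samples")
  if (anyNA(x) || any(!is.finite(x)))
    stopf("trial_entropy: samples must be finite")
  bins <- as.integer(bins)
  if (bins < 1L) stopf("trial_entropy: bins must be >= 1")
  r <- range(x)
  if (r[1] == r[2]) return(0)
  idx <- pmin(bins, floor((x - r[1]) / (r[2] - r[1]) * bins) + 1L)
  p <- tabulate(idx, bins) / length(x)
  p <- p[p > 0]
  switch(variant,
         shannon = -sum(p * log(p)),
         per_sample = -length(x) * sum(p * p * log(p)))
}

#' Mean per-channel entropy over trials
#'
#' Scores every channel by the mean of its per-trial amplitude-histogram
#' entropies: `h[l] = mean_m trial_entropy(x[m, l, ])`. Channels carrying
#' structured oscillatory activity spread their amplitudes more evenly
#' across the histogram than near-Gaussian noise does, and score higher.
#'
#' @param epoched an [epoched_eeg()] (conventionally after the broadband
#'   8--35 Hz filter).
#' @param bins histogram bin count (default 256).
#' @param per_trial keep the full M x L matrix of trial entropies?
#' @param variant see [trial_entropy()].
#' @return an `entropy_scores` object: `h` (length-L vector, nats), `bins`,
#'   and optionally `per_trial`.
#' @export
channel_entropy <- function(epoched, bins = 256L, per_trial = FALSE,
                            variant = "shannon") {
  stopifnot(inherits(epoched, "epoched_eeg"))
  d <- dim(epoched$data)
  ent <- matrix(0, d[1], d[2])
  for (m in seq_len(d[1])) {
    for (l in seq_len(d[2])) {
      ent[m, l] <- tryCatch(
        trial_entropy(epoched$data[m, l, ], bins = bins, variant = variant),
        error = function(e) stopf("channel_entropy: trial %d, channel %d: %s",
                                  m, l, conditionMessage(e)))
    }
  }
  structure(
    list(h = colMeans(ent), bins = as.integer(bins),
         channel_names = epoched$channel_names,
         per_trial = if (per_trial) ent else NULL),
    class = "entropy_scores")
}

#' Rank channels by entropy score
#'
#' Descending order of mean entropy; ties broken by ascending channel index
#' (stable), so equal-score rankings are reproducible.
#'
#' @param scores an `entropy_scores` object from [channel_entropy()].
#' @return a `channel_ranking` object: `order` (permutation of `1..L`, best
#'   first) and the scores.
#' @export
rank_channels <- function(scores) {
  stopifnot(inherits(scores, "entropy_scores"))
  h <- scores$h
  if (anyNA(h) || any(!is.finite(h)) || any(h < 0))
    stopf("rank_channels: scores must be finite and nonnegative")
  ord <- order(-h, seq_along(h))
  structure(list(order = ord, scores = scores), class = "channel_ranking")
}

#' @export
print.channel_ranking <- function(x, ...) {
  k <- min(10L, length(x$order))
  cat(sprintf("<channel_ranking> %d channels; top %d: %s\n",
              length(x$order), k,
              paste(sprintf("%s (%.3f)", x$scores$channel_names[x$order[1:k]],
                            x$scores$h[x$order[1:k]]), collapse = ", ")))
  invisible(x)
}

#' Restrict trials to the top-k ranked channels
#'
#' @param epoched an [epoched_eeg()].
#' @param ranking a `channel_ranking` from [rank_channels()].
#' @param k number of channels to keep, `1 <= k <= L`.
#' @return an [epoched_eeg()] whose channels are `ranking$order[1:k]`, in
#'   ranked order.
#' @export
select_channels <- function(epoched, ranking, k) {
  stopifnot(inherits(epoched, "epoched_eeg"), inherits(ranking, "channel_ranking"))
  L <- dim(epoched$data)[2]
  if (length(ranking$order) != L)
    stopf("select_channels: ranking is over %d channels, data has %d",
          length(ranking$order), L)
  k <- as.integer(k)
  if (k < 1L || k > L)
    stopf("select_channels: k = %d out of range [1, %d]", k, L)
  keep <- ranking$order[seq_len(k)]
  epoched_eeg(epoched$data[, keep, , drop = FALSE], fs = epoched$fs,
              channel_names = epoched$channel_names[keep],
              labels = epoched$labels)
}

#' Cross-validated accuracy as a function of channel count
#'
#' For each candidate `k`, runs the full leak-free cross-validated pipeline
#' (entropy ranking and selection, filter bank, CSP, classifier -- all fitted
#' inside training folds only) and records the mean accuracy. Typical use is
#' locating the channel count past which adding noisy channels stops
#' helping.
#'
#' @param epoched raw [epoched_eeg()] (broadband filtering is part of the
#'   evaluated pipeline).
#' @param ks integer vector of candidate channel counts; duplicates are
#'   dropped and values sorted.
#' @param config pipeline configuration, see [default_pipeline_config()].
#' @param folds number of cross-validation folds (default 5).
#' @param seed RNG seed for fold assignment and classifier initialisation.
#' @return a `channel_sweep` object: `table` (data frame with columns `k`,
#'   `accuracy`) and `best_k` (smallest `k` attaining the maximum accuracy).
#' @export
sweep_channel_count <- function(epoched, ks, config = default_pipeline_config(),
                                folds = 5L, seed = 1L) {
  stopifnot(inherits(epoched, "epoched_eeg"))
  L <- dim(epoched$data)[2]
  ks <- sort(unique(as.integer(ks)))
  if (any(ks < 1L) || any(ks > L))
    stopf("sweep_channel_count: ks must lie in [1, %d]", L)
  acc <- vapply(ks, function(k) {
    cfg <- config
    cfg$select_k <- k
    rep_k <- tryCatch(
      cross_validate(epoched, config = cfg, folds = folds, seed = seed),
      error = function(e) stopf("sweep (k = %d): %s", k, conditionMessage(e)))
    rep_k$summary$mean[rep_k$summary$metric == "accuracy"]
  }, numeric(1))
  tab <- data.frame(k = ks, accuracy = acc)
  structure(list(table = tab, best_k = ks[which.max(acc)]),
            class = "channel_sweep")
}

#' @export
print.channel_sweep <- function(x, ...) {
  cat("<channel_sweep>\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("best k: %d\n", x$best_k))
  invisible(x)
}
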