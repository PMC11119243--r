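# Common spatial patterns.
#
# CSP seeks spatial filters w maximizing the variance ratio
# w' B1 w / w' B2 w between the two classes' mean covariance matrices. The
# extremal directions are obtained from the equivalent, better conditioned
# generalized eigenproblem B1 w = lambda (B1 + B2) w: the eigenvectors with
# the largest lambda maximize class-1 variance share, those with the
# smallest maximize class-2's, and lambda always lies in [0, 1].

#' Trace-normalised class covariance matrices
#'
#' Each trial contributes `C_m = X X' / trace(X X')` (X the channels x
#' samples trial matrix); the class covariance is the mean of `C_m` over that
#' class's trials. Trace normalisation removes per-trial global amplitude so
#' the spatial structure, not overall power, drives the filters. Both class
#' matrices have unit trace.
#'
#' @param band_trials numeric array M x L x N (one sub-band's trials).
#' @param labels integer class labels in `{1, 2}`, length M; both classes
#'   must be present.
#' @return a `class_covariances` object with symmetric positive-semidefinite
#'   `B1`, `B2` and the channel count `L`.
#' @export
class_covariances <- function(band_trials, labels) {
  d <- dim(band_trials)
  if (length(d) != 3L) stopf("class_covariances: expected an M x L x N array")
  labels <- as.integer(labels)
  if (length(labels) != d[1]) stopf("class_covariances: %d labels for %d trials",
                                    length(labels), d[1])
  if (!all(labels %in% c(1L, 2L))) stopf("class_covariances: labels must be 1 or 2")
  tab <- tabulate(labels, 2L)
  if (any(tab == 0L))
    stopf("class_covariances: class %d has no trials", which(tab == 0L)[1])
  L <- d[2]
  acc <- list(matrix(0, L, L), matrix(0, L, L))
  for (m in seq_len(d[1])) {
    X <- matrix(band_trials[m, , ], nrow = L)
    C <- tcrossprod(X)
    tr <- sum(diag(C))
    if (tr <= 0)
      stopf("class_covariances: trial %d has zero total power", m)
    acc[[labels[m]]] <- acc[[labels[m]]] + C / tr
  }
  B1 <- acc[[1]] / tab[1]
  B2 <- acc[[2]] / tab[2]
  B1 <- (B1 + t(B1)) / 2
  B2 <- (B2 + t(B2)) / 2
  structure(list(B1 = B1, B2 = B2, L = L), class = "class_covariances")
}

#' Fit CSP spatial filters from class covariances
#'
#' Solves `B1 w = lambda (B1 + B2) w` by whitening the composite covariance
#' and keeps the eigenvectors of the `V` largest and `V` smallest
#' eigenvalues (columns ordered largest-first then smallest-last). Each
#' filter is scaled so `w' (B1 + B2) w = 1` and its sign fixed so the first
#' nonzero element is positive. A small shrinkage
#' `B <- (1 - reg) B + reg (trace(B)/L) I` guards against rank deficiency
#' when the channel count approaches the samples per trial.
#'
#' @param cov a `class_covariances` object.
#' @param V filter pairs per end; `2 * V` filters total, `2V <= L`.
#' @param reg shrinkage weight (default `1e-6`).
#' @return a `csp_model`: `W` (L x 2V filter matrix), `eigenvalues`
#'   (length 2V, each the class-1 variance share of its filter), `V`.
#' @export
fit_csp <- function(cov, V = 2L, reg = 1e-6) {
  stopifnot(inherits(cov, "class_covariances"))
  V <- as.integer(V)
  L <- cov$L
  if (V < 1L || 2L * V > L)
    stopf("fit_csp: need 1 <= 2V <= L (V = %d, L = %d)", V, L)
  shrink <- function(B) (1 - reg) * B + reg * (sum(diag(B)) / L) * diag(L)
  B1 <- shrink(cov$B1); B2 <- shrink(cov$B2)
  Cc <- B1 + B2
  ec <- eigen(Cc, symmetric = TRUE)
  if (min(ec$values) <= 1e-12 * max(ec$values))
    stopf("fit_csp: composite covariance is numerically singular; increase reg")
  P <- ec$vectors %*% (t(ec$vectors) / sqrt(ec$values))  # Cc^{-1/2}
  S1 <- P %*% B1 %*% P
  S1 <- (S1 + t(S1)) / 2
  e1 <- eigen(S1, symmetric = TRUE)      # descending eigenvalues in [0, 1]
  idx <- c(seq_len(V), seq(L - V + 1L, L))
  W <- P %*% e1$vectors[, idx, drop = FALSE]
  for (j in seq_len(ncol(W))) {
    nz <- which(W[, j] != 0)[1]
    if (!is.na(nz) && W[nz, j] < 0) W[, j] <- -W[, j]
  }
  structure(list(W = W, eigenvalues = e1$values[idx], V = V, L = L),
            class = "csp_model")
}

#' Log-variance CSP features for a set of trials
#'
#' Feature `(m, v)` is `log(var(w_v' X_m))`: the natural log of the sample
#' variance of trial `m` projected through filter `v`. The log transform
#' turns multiplicative amplitude changes into additive shifts. Projections
#' with zero variance are floored at `var + 1e-12` and flagged.
#'
#' @param band_trials numeric array M x L x N in the same band and channel
#'   space the model was fitted on.
#' @param model a `csp_model` from [fit_csp()].
#' @return M x 2V numeric matrix; attribute `floored` marks any
#'   zero-variance projections.
#' @export
band_features <- function(band_trials, model) {
  stopifnot(inherits(model, "csp_model"))
  d <- dim(band_trials)
  if (length(d) != 3L || d[2] != model$L)
    stopf("band_features: trials have %d channels, model expects %d",
          if (length(d) == 3L) d[2] else -1L, model$L)
  M <- d[1]; nf <- ncol(model$W)
  out <- matrix(0, M, nf)
  floored <- FALSE
  for (m in seq_len(M)) {
    X <- matrix(band_trials[m, , ], nrow = d[2])
    proj <- crossprod(model$W, X)           # 2V x N time courses
    v <- apply(proj, 1, stats::var)
    if (any(v == 0)) floored <- TRUE
    out[m, ] <- log(v + ifelse(v == 0, 1e-12, 0))
  }
  attr(out, "floored") <- floored
  out
}

#' Fit one CSP model per sub-band
#'
#' @param subbands a `subband_eeg` from [apply_filterbank()]; both classes
#'   must be present.
#' @param V filter pairs per end (default 2, giving 4 features per band).
#' @param reg covariance shrinkage, see [fit_csp()].
#' @return a `multiband_csp` object: list of per-band `csp_model`s, the band
#'   spec, and the channel names the filters are defined over.
#' @export
fit_multiband <- function(subbands, V = 2L, reg = 1e-6) {
  stopifnot(inherits(subbands, "subband_eeg"))
  S <- dim(subbands$data)[1]
  models <- vector("list", S)
  for (s in seq_len(S)) {
    cov_s <- tryCatch(
      class_covariances(array(subbands$data[s, , , ],
                              dim = dim(subbands$data)[2:4]),
                        subbands$labels),
      error = function(e) stopf("fit_multiband: band %d: %s", s,
                                conditionMessage(e)))
    models[[s]] <- fit_csp(cov_s, V = V, reg = reg)
  }
  structure(list(models = models, spec = subbands$spec,
                 channel_names = subbands$channel_names, V = as.integer(V)),
            class = "multiband_csp")
}

#' Concatenated multiband feature matrix
#'
#' Extracts log-variance features from every band and concatenates them
#' band-major: columns `(s - 1) * 2V + v`. With the default four bands and
#' `V = 2` each trial yields a 16-dimensional feature vector.
#'
#' @param subbands a `subband_eeg`; its bands and channel space must match
#'   the model's.
#' @param model a `multiband_csp` from [fit_multiband()].
#' @return M x (S * 2V) matrix with band/filter column names and the trial
#'   labels as attribute `labels`.
#' @export
extract_features <- function(subbands, model) {
  stopifnot(inherits(subbands, "subband_eeg"), inherits(model, "multiband_csp"))
  S <- dim(subbands$data)[1]
  if (S != length(model$models))
    stopf("extract_features: %d bands in data, model has %d", S,
          length(model$models))
  if (!identical(subbands$channel_names, model$channel_names))
    stopf("extract_features: channel set differs from the one the model was fitted on")
  blocks <- vector("list", S)
  for (s in seq_len(S)) {
    blocks[[s]] <- band_features(
      array(subbands$data[s, , , ], dim = dim(subbands$data)[2:4]),
      model$models[[s]])
    band <- model$spec$bands[[s]]
    colnames(blocks[[s]]) <- sprintf("b%d_%g.%gHz_f%d", s, band[1], band[2],
                                     seq_len(ncol(blocks[[s]])))
  }
  out <- do.call(cbind, blocks)
  attr(out, "labels") <- subbands$labels
  out
}
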