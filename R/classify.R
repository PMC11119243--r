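#' Classifier specification
#'
#' Three classifier families are supported:
#' \describe{
#'   \item{`svm_rbf`}{support vector machine with a radial basis function
#'     kernel (via \pkg{e1071}); `C` is the soft-margin cost and `gamma`
#'     the kernel width. When `gamma` is `NULL` it is set from the data as
#'     `1 / (2 * sigma^2)` with `sigma` the median pairwise feature
#'     distance (median heuristic).}
#'   \item{`lda`}{linear discriminant with pooled within-class covariance,
#'     ridge-regularised by `ridge * mean(diag)` for numerical safety.}
#'   \item{`ann`}{feed-forward network (via \pkg{nnet}) with one hidden
#'     layer of `hidden_size` sigmoid units and a linear output layer of
#'     size 2 (one unit per class); trained by BFGS up to `max_epochs`
#'     iterations from a seeded random initialisation.}
#' }
#'
#' @param kind `"svm_rbf"`, `"lda"` or `"ann"`.
#' @param C SVM cost (> 0), default 1.
#' @param gamma SVM kernel coefficient, or `NULL` for the median heuristic.
#' @param ridge LDA covariance ridge, default `1e-6`.
#' @param hidden_size ANN hidden units (default 10).
#' @param max_epochs ANN optimisation iteration cap (default 500).
#' @param seed RNG seed for the ANN's weight initialisation.
#' @return a `classifier_spec` object.
#' @export
classifier_spec <- function(kind = c("svm_rbf", "lda", "ann"), C = 1,
                            gamma = NULL, ridge = 1e-6, hidden_size = 10L,
                            max_epochs = 500L, seed = 1L) {
  kind <- match.arg(kind)
  if (C <= 0) stopf("classifier_spec: C must be positive")
  hidden_size <- as.integer(hidden_size)
  if (hidden_size < 1L) stopf("classifier_spec: hidden_size must be >= 1")
  structure(list(kind = kind, C = C, gamma = gamma, ridge = ridge,
                 hidden_size = hidden_size,
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Train a two-class classifier on a feature matrix
#'
#' @param features numeric M x D matrix (e.g. from [extract_features()]).
#' @param labels integer labels in `{1, 2}`, length M; both classes must
#'   have at least two trials.
#' @param spec a [classifier_spec()].
#' @return a fitted `micsel_classifier`; predictions via
#'   [predict_classifier()]. Deterministic given the spec (including its
#'   seed).
#' @export
train_classifier <- function(features, labels, spec = classifier_spec()) {
  stopifnot(inherits(spec, "classifier_spec"))
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (nrow(features) != length(labels))
    stopf("train_classifier: %d rows of features for %d labels",
          nrow(features), length(labels))
  if (anyNA(features) || any(!is.finite(features)))
    stopf("train_classifier: features must be finite")
  if (!all(labels %in% c(1L, 2L)))
    stopf("train_classifier: labels must be 1 or 2")
  tab <- tabulate(labels, 2L)
  if (any(tab < 2L))
    stopf("train_classifier: need >= 2 trials per class (counts: %d, %d)",
          tab[1], tab[2])
  fit <- switch(spec$kind,
    svm_rbf = {
      gamma <- spec$gamma
      if (is.null(gamma)) {
        sigma <- stats::median(stats::dist(features))
        gamma <- if (is.finite(sigma) && sigma > 0) 1 / (2 * sigma^2)
                 else 1 / ncol(features)
      }
      e1071::svm(features, factor(labels, levels = c(1L, 2L)),
                 kernel = "radial", cost = spec$C, gamma = gamma,
                 scale = FALSE)
    },
    lda = {
      mu <- lapply(1:2, function(c) colMeans(features[labels == c, , drop = FALSE]))
      Sw <- matrix(0, ncol(features), ncol(features))
      for (c in 1:2) {
        Xc <- sweep(features[labels == c, , drop = FALSE], 2, mu[[c]])
        Sw <- Sw + crossprod(Xc)
      }
      Sw <- Sw / (nrow(features) - 2L)
      Sw <- Sw + spec$ridge * mean(diag(Sw)) * diag(ncol(features))
      w <- solve(Sw, mu[[1]] - mu[[2]])
      b <- -0.5 * sum(w * (mu[[1]] + mu[[2]])) + log(tab[1] / tab[2])
      list(w = w, b = b)
    },
    ann = {
      y_ind <- cbind(as.numeric(labels == 1L), as.numeric(labels == 2L))
      with_seed(spec$seed,
        nnet::nnet(features, y_ind, size = spec$hidden_size, linout = TRUE,
                   maxit = spec$max_epochs, trace = FALSE))
    })
  structure(list(kind = spec$kind, fit = fit, spec = spec,
                 n_features = ncol(features)),
            class = "micsel_classifier")
}

#' Predict class labels from a fitted classifier
#'
#' @param model a `micsel_classifier` from [train_classifier()].
#' @param features numeric matrix with the same columns as the training
#'   features.
#' @return integer vector of predicted labels in `{1, 2}`.
#' @export
predict_classifier <- function(model, features) {
  stopifnot(inherits(model, "micsel_classifier"))
  features <- as.matrix(features)
  if (ncol(features) != model$n_features)
    stopf("predict_classifier: %d feature columns, model expects %d",
          ncol(features), model$n_features)
  switch(model$kind,
    svm_rbf = as.integer(as.character(predict(model$fit, features))),
    lda = ifelse(drop(features %*% model$fit$w) + model$fit$b > 0, 1L, 2L),
    ann = {
      scores <- predict(model$fit, features)
      ifelse(scores[, 1] >= scores[, 2], 1L, 2L)
    })
}

#' Confusion-matrix classification metrics
#'
#' Class 1 is the positive class. Accuracy is
#' `(TP + TN) / (TP + FP + TN + FN)`, precision `TP / (TP + FP)`, recall
#' `TP / (TP + FN)` and F1 the harmonic mean of precision and recall. A
#' ratio with zero denominator is reported as 0 and named in the
#' `undefined` attribute rather than propagating `NaN`.
#'
#' @param y_true,y_pred integer label vectors over `{1, 2}`, equal length.
#' @return a `micsel_metrics` object: `accuracy`, `precision`, `recall`,
#'   `f1`, and the `confusion` counts (TP, FP, TN, FN).
#' @export
confusion_metrics <- function(y_true, y_pred) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred))
    stopf("confusion_metrics: length mismatch (%d vs %d)",
          length(y_true), length(y_pred))
  if (!all(c(y_true, y_pred) %in% c(1L, 2L)))
    stopf("confusion_metrics: labels must be 1 (positive) or 2 (negative)")
  TP <- sum(y_true == 1L & y_pred == 1L)
  FN <- sum(y_true == 1L & y_pred == 2L)
  FP <- sum(y_true == 2L & y_pred == 1L)
  TN <- sum(y_true == 2L & y_pred == 2L)
  undefined <- character(0)
  safe_div <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); 0 } else num / den
  }
  accuracy <- safe_div(TP + TN, TP + FP + TN + FN, "accuracy")
  precision <- safe_div(TP, TP + FP, "precision")
  recall <- safe_div(TP, TP + FN, "recall")
  f1 <- safe_div(2 * precision * recall, precision + recall, "f1")
  structure(list(accuracy = accuracy, precision = precision, recall = recall,
                 f1 = f1, confusion = c(TP = TP, FP = FP, TN = TN, FN = FN),
                 undefined = undefined),
            class = "micsel_metrics")
}

# Stratified fold assignment: within each class, shuffled trials are dealt
# round-robin over folds so class proportions stay balanced. Falls back to
# plain shuffled assignment when folds exceed the smaller class count
# (e.g. leave-one-out).
make_folds <- function(labels, folds, seed) {
  M <- length(labels)
  if (folds < 2L || folds > M)
    stopf("cross_validate: folds must lie in [2, %d]", M)
  with_seed(seed, {
    assign_f <- integer(M)
    if (folds <= min(tabulate(labels, 2L))) {
      for (c in 1:2) {
        idx <- sample(which(labels == c))
        assign_f[idx] <- rep_len(seq_len(folds), length(idx))
      }
    } else {
      assign_f[sample.int(M)] <- rep_len(seq_len(folds), M)
    }
    assign_f
  })
}

#' Leak-free cross-validated evaluation of the full pipeline
#'
#' Runs stratified k-fold cross-validation of the complete chain: broadband
#' 8--35 Hz filtering, entropy-based channel ranking and selection, sub-band
#' decomposition, per-band CSP, feature fusion and classification. All
#' data-dependent fitting (entropy scores, selected channel set, CSP
#' filters, classifier) uses training-fold trials only; test trials are only
#' transformed and scored. Set `config$leaky_selection = TRUE` to instead
#' rank channels on the whole dataset before splitting -- useful for
#' comparison with protocols that select channels globally, but it leaks
#' test information into the channel choice.
#'
#' @param epoched raw [epoched_eeg()] trials with labels.
#' @param config pipeline settings, see [default_pipeline_config()].
#' @param folds number of folds (default 5).
#' @param seed seed for fold assignment and classifier initialisation.
#' @return an `eval_report`: per-fold `micsel_metrics`, a `summary` data
#'   frame (mean and sd per metric), the fold assignment, the selected
#'   channels per fold, and the resolved configuration.
#' @export
cross_validate <- function(epoched, config = default_pipeline_config(),
                           folds = 5L, seed = 1L) {
  stopifnot(inherits(epoched, "epoched_eeg"))
  config <- resolve_config(config)
  folds <- as.integer(folds)
  check_two_classes(epoched)
  d <- dim(epoched$data)
  assign_f <- make_folds(epoched$labels, folds, seed)

  bb <- config$broadband
  broad <- eeg_bandpass(epoched, bandpass_spec(bb$low_hz, bb$high_hz,
                                               bb$order, bb$zero_phase))
  fb_spec <- filterbank_spec(config$filterbank$bands, config$filterbank$order)
  k <- config$select_k
  if (!is.null(k) && (k < 1L || k > d[2]))
    stopf("cross_validate: select_k = %d out of range [1, %d]", k, d[2])

  global_ranking <- if (isTRUE(config$leaky_selection) && !is.null(k))
    rank_channels(channel_entropy(broad, bins = config$entropy$bins)) else NULL

  subset_trials <- function(eeg, idx)
    epoched_eeg(eeg$data[idx, , , drop = FALSE], eeg$fs, eeg$channel_names,
                eeg$labels[idx])

  fold_metrics <- vector("list", folds)
  fold_channels <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr_idx <- which(assign_f != f)
    te_idx <- which(assign_f == f)
    train <- subset_trials(broad, tr_idx)
    test <- subset_trials(broad, te_idx)
    if (any(tabulate(train$labels, 2L) == 0L))
      stopf("cross_validate: fold %d training partition lacks a class; use fewer folds", f)
    if (!is.null(k)) {
      ranking <- global_ranking %||%
        rank_channels(channel_entropy(train, bins = config$entropy$bins))
      train <- select_channels(train, ranking, k)
      test <- select_channels(test, ranking, k)
    }
    sb_train <- apply_filterbank(train, fb_spec)
    sb_test <- apply_filterbank(test, fb_spec)
    # with very few selected channels, fewer filter pairs fit: cap V at L'/2
    V_eff <- min(config$csp$V, dim(train$data)[2] %/% 2L)
    model <- fit_multiband(sb_train, V = V_eff, reg = config$csp$reg)
    feat_train <- extract_features(sb_train, model)
    feat_test <- extract_features(sb_test, model)
    cspec <- classifier_spec(kind = config$classifier$kind,
                             C = config$classifier$C,
                             gamma = config$classifier$gamma,
                             ridge = config$classifier$ridge,
                             hidden_size = config$classifier$hidden_size,
                             max_epochs = config$classifier$max_epochs,
                             seed = seed + f)
    clf <- train_classifier(feat_train, train$labels, cspec)
    pred <- predict_classifier(clf, feat_test)
    fold_metrics[[f]] <- confusion_metrics(test$labels, pred)
    fold_channels[[f]] <- train$channel_names
  }

  metric_names <- c("accuracy", "precision", "recall", "f1")
  vals <- sapply(metric_names, function(nm)
    vapply(fold_metrics, function(mt) mt[[nm]], numeric(1)))
  summary_df <- data.frame(
    metric = metric_names,
    mean = colMeans(vals),
    sd = apply(vals, 2, stats::sd),
    row.names = NULL)
  structure(
    list(folds = fold_metrics, summary = summary_df,
         fold_assignment = assign_f, selected_channels = fold_channels,
         config = config, n_folds = folds, seed = seed),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d-fold cross-validation (%s classifier)\n",
              x$n_folds, x$config$classifier$kind))
  df <- x$summary
  df$mean <- sprintf("%.4f", df$mean)
  df$sd <- sprintf("%.4f", df$sd)
  print(df, row.names = FALSE)
  invisible(x)
}
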