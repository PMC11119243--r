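#' Default pipeline configuration
#'
#' Nested list of every tunable stage parameter with the package defaults:
#' broadband 8--35 Hz fifth-order zero-phase Butterworth; 256-bin entropy
#' histograms; `select_k = NULL` (keep all channels -- set an integer, or
#' use [sweep_channel_count()] to pick one); the four-band mu/beta filter
#' bank at order 5; CSP with `V = 2` filter pairs per end and `1e-6`
#' covariance shrinkage; RBF-SVM classifier with `C = 1` and
#' median-heuristic kernel width.
#'
#' @return nested configuration list accepted by [cross_validate()],
#'   [sweep_channel_count()] and [run_pipeline()].
#' @export
default_pipeline_config <- function() {
  list(
    broadband = list(low_hz = 8, high_hz = 35, order = 5L, zero_phase = TRUE),
    entropy = list(bins = 256L),
    select_k = NULL,
    filterbank = list(bands = default_bands(), order = 5L),
    csp = list(V = 2L, reg = 1e-6),
    classifier = list(kind = "svm_rbf", C = 1, gamma = NULL, ridge = 1e-6,
                      hidden_size = 10L, max_epochs = 500L),
    leaky_selection = FALSE
  )
}

# Merge a partial user config over the defaults and validate the result
# before any computation runs.
resolve_config <- function(config) {
  def <- default_pipeline_config()
  if (is.null(config)) return(def)
  if (!is.list(config)) stopf("config must be a list")
  cfg <- utils::modifyList(def, config)
  with(cfg$broadband, {
    if (!(low_hz > 0 && high_hz > low_hz)) stopf("config: invalid broadband band")
    if (order < 1L) stopf("config: broadband order must be >= 1")
  })
  if (cfg$entropy$bins < 1L) stopf("config: entropy bins must be >= 1")
  if (!is.null(cfg$select_k)) cfg$select_k <- as.integer(cfg$select_k)
  filterbank_spec(cfg$filterbank$bands, cfg$filterbank$order)
  if (cfg$csp$V < 1L) stopf("config: csp V must be >= 1")
  if (!cfg$classifier$kind %in% c("svm_rbf", "lda", "ann"))
    stopf("config: unknown classifier kind '%s'", cfg$classifier$kind)
  cfg
}

#' Run the full channel-selection pipeline and write its artifacts
#'
#' Convenience driver: evaluates the configured pipeline with leak-free
#' cross-validation, then refits the whole chain on all trials to export the
#' final channel ranking, feature matrix and multiband CSP model. Writes
#' `ranking.csv`, `features.csv`, `model.json` and `report.json` under
#' `out_dir`.
#'
#' @param dataset an [epoched_eeg()] or a path readable by [load_native()].
#' @param config pipeline settings (partial lists are merged over
#'   [default_pipeline_config()]).
#' @param out_dir output directory, created if needed; `NULL` writes
#'   nothing.
#' @param folds,seed cross-validation folds and seed.
#' @return the `eval_report`, invisibly augmented with the final ranking
#'   (`$final_ranking`) and model (`$final_model`).
#' @export
run_pipeline <- function(dataset, config = default_pipeline_config(),
                         out_dir = NULL, folds = 5L, seed = 1L) {
  if (is.character(dataset)) dataset <- load_native(dataset)
  if (inherits(dataset, "continuous_eeg"))
    stopf("run_pipeline: epoch the recording first (see epoch_trials())")
  stopifnot(inherits(dataset, "epoched_eeg"))
  config <- resolve_config(config)

  report <- cross_validate(dataset, config = config, folds = folds, seed = seed)

  bb <- config$broadband
  broad <- eeg_bandpass(dataset, bandpass_spec(bb$low_hz, bb$high_hz,
                                               bb$order, bb$zero_phase))
  ranking <- rank_channels(channel_entropy(broad, bins = config$entropy$bins))
  selected <- if (!is.null(config$select_k))
    select_channels(broad, ranking, config$select_k) else
    select_channels(broad, ranking, dim(broad$data)[2])
  subbands <- apply_filterbank(
    selected, filterbank_spec(config$filterbank$bands, config$filterbank$order))
  V_eff <- min(config$csp$V, dim(selected$data)[2] %/% 2L)
  model <- fit_multiband(subbands, V = V_eff, reg = config$csp$reg)
  features <- extract_features(subbands, model)

  report$final_ranking <- ranking
  report$final_model <- model

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    rank_df <- data.frame(
      channel_name = ranking$scores$channel_names[ranking$order],
      score = ranking$scores$h[ranking$order],
      rank = seq_along(ranking$order))
    data.table::fwrite(rank_df, file.path(out_dir, "ranking.csv"))
    feat_df <- data.frame(label = attr(features, "labels"), features,
                          check.names = FALSE)
    data.table::fwrite(feat_df, file.path(out_dir, "features.csv"))
    model_json <- list(
      bands = model$spec$bands,
      V = model$V,
      channel_names = model$channel_names,
      filters = lapply(model$models, function(m) {
        list(W = unclass(m$W), eigenvalues = m$eigenvalues)
      }))
    jsonlite::write_json(model_json, file.path(out_dir, "model.json"),
                         auto_unbox = TRUE, digits = NA)
    report_json <- list(
      n_folds = report$n_folds, seed = report$seed,
      summary = report$summary,
      per_fold = lapply(report$folds, function(mt)
        c(mt[c("accuracy", "precision", "recall", "f1")],
          list(confusion = as.list(mt$confusion)))),
      selected_channels = report$selected_channels,
      config = config_for_json(config))
    jsonlite::write_json(report_json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}

config_for_json <- function(cfg) {
  cfg$select_k <- cfg$select_k %||% "all"
  cfg$classifier$gamma <- cfg$classifier$gamma %||% "median_heuristic"
  cfg
}
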