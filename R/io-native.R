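# Native plain-text dataset container.
#
# A dataset directory holds manifest.json plus CSV payloads. Two dialects,
# chosen by the manifest's "storage" field:
#   "csv"        - one CSV per trial (data_trial0001.csv, ...), samples as
#                  rows and channels as columns; human-diffable fixtures.
#   "csv_single" - one data.csv with all trials stacked (M x N rows, L
#                  columns); faster for large simulations.
# Continuous recordings always use data.csv (T x L) plus events.csv.
# Numbers are written as %.17g so values round-trip bitwise.

fmt_num <- function(m) {
  out <- array(sprintf("%.17g", m), dim = dim(m))
  out
}

write_matrix_csv <- function(mat, path, col_names) {
  dt <- data.table::as.data.table(fmt_num(mat))
  data.table::setnames(dt, col_names)
  data.table::fwrite(dt, path, quote = FALSE)
}

read_matrix_csv <- function(path, expect_cols = NULL) {
  dt <- data.table::fread(path, colClasses = "numeric", header = TRUE)
  m <- as.matrix(dt)
  dimnames(m) <- NULL
  m
}

#' Save a dataset in the native container format
#'
#' Writes `manifest.json` and CSV payloads into `path` (created if needed)
#' so that [load_native()] reconstructs an equal object. See the package
#' source notes for the layout.
#'
#' @param dataset an [epoched_eeg()] or [continuous_eeg()].
#' @param path target directory.
#' @param storage `"csv"` (one file per trial) or `"csv_single"` (one
#'   stacked file); ignored for continuous recordings.
#' @param label_map optional named list documenting the original label
#'   coding (stored verbatim in the manifest).
#' @return `path`, invisibly.
#' @export
save_native <- function(dataset, path, storage = c("csv", "csv_single"),
                        label_map = list(`1` = 1, `2` = 2)) {
  storage <- match.arg(storage)
  ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stopf("save_native: cannot create directory '%s'", path)
  if (inherits(dataset, "epoched_eeg")) {
    d <- dim(dataset$data)
    manifest <- list(
      type = "epoched", storage = storage, fs = dataset$fs,
      n_trials = d[1], n_channels = d[2], n_samples = d[3],
      channel_names = dataset$channel_names,
      labels = dataset$labels, label_map = label_map)
    if (storage == "csv") {
      for (m in seq_len(d[1])) {
        write_matrix_csv(t(matrix(dataset$data[m, , ], nrow = d[2])),
                         file.path(path, sprintf("data_trial%04d.csv", m)),
                         dataset$channel_names)
      }
    } else {
      flat <- matrix(0, d[1] * d[3], d[2])
      for (m in seq_len(d[1]))
        flat[((m - 1L) * d[3] + 1L):(m * d[3]), ] <-
          t(matrix(dataset$data[m, , ], nrow = d[2]))
      write_matrix_csv(flat, file.path(path, "data.csv"),
                       dataset$channel_names)
    }
  } else if (inherits(dataset, "continuous_eeg")) {
    manifest <- list(
      type = "continuous", storage = "csv", fs = dataset$fs,
      n_channels = nrow(dataset$data), n_samples = ncol(dataset$data),
      channel_names = dataset$channel_names, label_map = label_map)
    write_matrix_csv(t(dataset$data), file.path(path, "data.csv"),
                     dataset$channel_names)
    ev <- dataset$events
    ev$label <- ifelse(is.na(ev$label), "", as.character(ev$label))
    data.table::fwrite(ev, file.path(path, "events.csv"), quote = FALSE)
  } else stopf("save_native: expected an epoched_eeg or continuous_eeg")
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a dataset from the native container format
#'
#' Reads `manifest.json` and the payload files written by [save_native()],
#' validating that payload dimensions match the manifest before
#' constructing the (self-validating) EEG object -- malformed containers are
#' rejected here, never deep in the pipeline.
#'
#' @param path dataset directory.
#' @return an [epoched_eeg()] or [continuous_eeg()] per the manifest's
#'   `type`.
#' @export
load_native <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path))
    stopf("load_native: no manifest.json under '%s'", path)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  for (field in c("type", "fs", "n_channels", "channel_names"))
    if (is.null(mf[[field]]))
      stopf("load_native: manifest missing field '%s'", field)
  L <- as.integer(mf$n_channels)
  if (length(mf$channel_names) != L)
    stopf("load_native: manifest lists %d channel names for n_channels = %d",
          length(mf$channel_names), L)
  if (mf$type == "epoched") {
    M <- as.integer(mf$n_trials); N <- as.integer(mf$n_samples)
    data <- array(0, dim = c(M, L, N))
    if (identical(mf$storage, "csv_single")) {
      flat <- read_matrix_csv(file.path(path, "data.csv"))
      if (!all(dim(flat) == c(M * N, L)))
        stopf("load_native: data.csv is %d x %d, manifest expects %d x %d",
              nrow(flat), ncol(flat), M * N, L)
      for (m in seq_len(M))
        data[m, , ] <- t(flat[((m - 1L) * N + 1L):(m * N), , drop = FALSE])
    } else {
      for (m in seq_len(M)) {
        f <- file.path(path, sprintf("data_trial%04d.csv", m))
        if (!file.exists(f)) stopf("load_native: missing payload '%s'", f)
        tm <- read_matrix_csv(f)
        if (!all(dim(tm) == c(N, L)))
          stopf("load_native: trial %d payload is %d x %d, manifest expects %d x %d",
                m, nrow(tm), ncol(tm), N, L)
        data[m, , ] <- t(tm)
      }
    }
    epoched_eeg(data, fs = mf$fs, channel_names = mf$channel_names,
                labels = as.integer(mf$labels))
  } else if (mf$type == "continuous") {
    T_len <- as.integer(mf$n_samples)
    tm <- read_matrix_csv(file.path(path, "data.csv"))
    if (!all(dim(tm) == c(T_len, L)))
      stopf("load_native: data.csv is %d x %d, manifest expects %d x %d",
            nrow(tm), ncol(tm), T_len, L)
    ev_path <- file.path(path, "events.csv")
    events <- if (file.exists(ev_path)) {
      ev <- data.table::fread(ev_path, header = TRUE,
                              colClasses = list(integer = "sample"))
      data.frame(sample = as.integer(ev$sample),
                 label = suppressWarnings(as.integer(ev$label)))
    } else NULL
    continuous_eeg(t(tm), fs = mf$fs, channel_names = mf$channel_names,
                   events = events)
  } else stopf("load_native: unknown dataset type '%s'", mf$type)
}
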