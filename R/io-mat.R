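# Minimal MATLAB v5 MAT-file reader.
#
# Supports the subset of the format the BCI-competition downloads use:
# little-endian files, numeric arrays (int8..int32, single, double), char
# arrays, cell arrays, structs, and zlib-compressed top-level elements.
# No installed R package reads MAT v5, so the binary layout is parsed here
# directly; anything outside the supported subset fails with a named error.

MI_TYPES <- c(miINT8 = 1, miUINT8 = 2, miINT16 = 3, miUINT16 = 4,
              miINT32 = 5, miUINT32 = 6, miSINGLE = 7, miDOUBLE = 9,
              miMATRIX = 14, miCOMPRESSED = 15, miUTF8 = 16)

mi_size <- function(type) switch(as.character(type),
  "1" = 1L, "2" = 1L, "3" = 2L, "4" = 2L, "5" = 4L, "6" = 4L,
  "7" = 4L, "9" = 8L, "16" = 1L,
  stopf("mat5: unsupported data type %d", type))

mi_read_numeric <- function(bytes, type) {
  n <- length(bytes) %/% mi_size(type)
  switch(as.character(type),
    "1" = as.numeric(readBin(bytes, integer(), n, size = 1, signed = TRUE)),
    "2" = as.numeric(readBin(bytes, integer(), n, size = 1, signed = FALSE)),
    "3" = as.numeric(readBin(bytes, integer(), n, size = 2, signed = TRUE,
                             endian = "little")),
    "4" = as.numeric(readBin(bytes, integer(), n, size = 2, signed = FALSE,
                             endian = "little")),
    "5" = as.numeric(readBin(bytes, integer(), n, size = 4, endian = "little")),
    "6" = {
      v <- as.numeric(readBin(bytes, integer(), n, size = 4, endian = "little"))
      ifelse(v < 0, v + 2^32, v)
    },
    "7" = readBin(bytes, double(), n, size = 4, endian = "little"),
    "9" = readBin(bytes, double(), n, size = 8, endian = "little"),
    stopf("mat5: unsupported numeric type %d", type))
}

# Reads the tag at pos; returns type, nbytes, data offset, and offset of the
# next element (data padded to 8-byte boundaries; small element format packs
# <= 4 bytes into the tag itself).
mat5_tag <- function(raw, pos) {
  word <- readBin(raw[pos:(pos + 3L)], integer(), 1, size = 4,
                  endian = "little")
  if (word < 0) word <- word + 2^32
  small_len <- word %/% 65536
  if (small_len > 0) {
    list(type = word %% 65536, nbytes = small_len, data_at = pos + 4L,
         next_at = pos + 8L)
  } else {
    nbytes <- readBin(raw[(pos + 4L):(pos + 7L)], integer(), 1, size = 4,
                      endian = "little")
    if (nbytes < 0) nbytes <- nbytes + 2^32
    padded <- if (word == MI_TYPES["miCOMPRESSED"]) nbytes
              else ((nbytes + 7L) %/% 8L) * 8L
    list(type = word, nbytes = nbytes, data_at = pos + 8L,
         next_at = pos + 8L + padded)
  }
}

tag_bytes <- function(raw, tag) {
  if (tag$nbytes == 0L) return(raw[0])
  raw[tag$data_at:(tag$data_at + tag$nbytes - 1L)]
}

# Parses one miMATRIX payload; returns list(name = , value = ).
mat5_matrix <- function(bytes) {
  pos <- 1L
  # array flags
  tg <- mat5_tag(bytes, pos)
  flags <- readBin(tag_bytes(bytes, tg)[1:4], integer(), 1, size = 4,
                   endian = "little")
  mx_class <- flags %% 256
  pos <- tg$next_at
  # dimensions
  tg <- mat5_tag(bytes, pos)
  dims <- as.integer(mi_read_numeric(tag_bytes(bytes, tg), tg$type))
  pos <- tg$next_at
  # name
  tg <- mat5_tag(bytes, pos)
  name <- rawToChar(tag_bytes(bytes, tg))
  pos <- tg$next_at

  value <- if (mx_class %in% 6:13) {           # numeric classes
    tg <- mat5_tag(bytes, pos)
    v <- mi_read_numeric(tag_bytes(bytes, tg), tg$type)
    pos <- tg$next_at
    out <- array(v, dim = dims)
    if (length(dims) == 2L && any(dims == 1L)) out <- as.vector(out)
    attr(out, "mat_class") <- mx_class
    out
  } else if (mx_class == 4) {                  # char
    tg <- mat5_tag(bytes, pos)
    b <- tag_bytes(bytes, tg)
    chars <- if (tg$type %in% c(4, 17)) {
      intToUtf8(readBin(b, integer(), length(b) %/% 2L, size = 2,
                        signed = FALSE, endian = "little"), multiple = TRUE)
    } else intToUtf8(as.integer(b), multiple = TRUE)
    paste(chars, collapse = "")
  } else if (mx_class == 1) {                  # cell
    n <- prod(dims)
    out <- vector("list", n)
    for (i in seq_len(n)) {
      tg <- mat5_tag(bytes, pos)
      out[[i]] <- mat5_matrix(tag_bytes(bytes, tg))$value
      pos <- tg$next_at
    }
    out
  } else if (mx_class == 2) {                  # struct
    tg <- mat5_tag(bytes, pos)
    name_len <- as.integer(mi_read_numeric(tag_bytes(bytes, tg), tg$type))
    pos <- tg$next_at
    tg <- mat5_tag(bytes, pos)
    fn_raw <- tag_bytes(bytes, tg)
    n_fields <- length(fn_raw) %/% name_len
    fields <- vapply(seq_len(n_fields), function(i) {
      chunk <- fn_raw[((i - 1L) * name_len + 1L):(i * name_len)]
      rawToChar(chunk[chunk != as.raw(0)])
    }, "")
    pos <- tg$next_at
    n_elem <- prod(dims)
    if (n_elem != 1L)
      stopf("mat5: struct arrays larger than 1x1 are not supported")
    out <- vector("list", n_fields)
    names(out) <- fields
    for (i in seq_len(n_fields)) {
      tg <- mat5_tag(bytes, pos)
      out[[i]] <- mat5_matrix(tag_bytes(bytes, tg))$value
      pos <- tg$next_at
    }
    out
  } else stopf("mat5: unsupported array class %d", mx_class)
  list(name = name, value = value)
}

#' Read a MATLAB v5 MAT-file
#'
#' Parses little-endian MAT v5 files containing numeric arrays, char
#' arrays, cells and 1x1 structs (including zlib-compressed variables) into
#' a named list. This covers the layout of the BCI-competition motor-imagery
#' downloads; files outside the subset fail with a descriptive error.
#'
#' @param path MAT-file path.
#' @return named list of variables; numeric arrays carry the MATLAB storage
#'   class as attribute `mat_class`.
#' @export
read_mat5 <- function(path) {
  raw <- readBin(path, raw(), file.size(path))
  if (length(raw) < 128L) stopf("mat5: '%s' is too short to be a MAT v5 file", path)
  endian <- rawToChar(raw[127:128])
  if (endian == "MI")
    stopf("mat5: big-endian MAT-files are not supported")
  if (endian != "IM")
    stopf("mat5: '%s' lacks a MAT v5 header", path)
  vars <- list()
  pos <- 129L
  while (pos + 7L <= length(raw)) {
    tg <- mat5_tag(raw, pos)
    payload <- tag_bytes(raw, tg)
    if (tg$type == MI_TYPES["miCOMPRESSED"]) {
      inflated <- tryCatch(memDecompress(payload, type = "gzip"),
                           error = function(e)
                             stopf("mat5: failed to inflate compressed variable: %s",
                                   conditionMessage(e)))
      itg <- mat5_tag(inflated, 1L)
      if (itg$type != MI_TYPES["miMATRIX"])
        stopf("mat5: unexpected element type %d inside compressed block", itg$type)
      el <- mat5_matrix(tag_bytes(inflated, itg))
    } else if (tg$type == MI_TYPES["miMATRIX"]) {
      el <- mat5_matrix(payload)
    } else {
      stopf("mat5: unexpected top-level element type %d", tg$type)
    }
    vars[[el$name]] <- el$value
    pos <- tg$next_at
  }
  vars
}

#' Load a BCI-competition continuous recording from a MAT-file
#'
#' Expects the layout the BCI Competition III-IVa and IV-I motor-imagery
#' downloads use: a continuous signal `cnt` (samples x channels; int16
#' counts of 0.1 microvolt, or plain double microvolts), a marker struct
#' `mrk` with cue positions `pos` (1-based samples) and classes `y`, and an
#' info struct `nfo` with sampling rate `fs` and channel labels `clab`.
#'
#' Class coding differs between the layouts and is normalised to `{1, 2}`:
#' `iii_iva` uses `y` in `{1, 2}` (NaN for unlabeled test trials);
#' `iv_i` uses `y` in `{-1, +1}`, mapped to 1 and 2. Unlabeled markers are
#' kept with an `NA` label.
#'
#' @param path MAT-file path.
#' @param layout `"iii_iva"` or `"iv_i"`.
#' @return a [continuous_eeg()] with events at the cue positions.
#' @export
load_bci_competition_mat <- function(path, layout = c("iii_iva", "iv_i")) {
  layout <- match.arg(layout)
  vars <- read_mat5(path)
  for (v in c("cnt", "mrk", "nfo"))
    if (is.null(vars[[v]]))
      stopf("load_bci_competition_mat: variable '%s' missing from '%s'", v, path)
  for (fld in c("pos", "y"))
    if (is.null(vars$mrk[[fld]]))
      stopf("load_bci_competition_mat: marker struct lacks field '%s'", fld)
  for (fld in c("fs", "clab"))
    if (is.null(vars$nfo[[fld]]))
      stopf("load_bci_competition_mat: info struct lacks field '%s'", fld)
  cnt <- vars$cnt
  # int16 counts are 0.1 microvolt per the competition documentation
  scale <- if (identical(attr(cnt, "mat_class"), 10)) 0.1 else 1
  data <- t(array(as.numeric(cnt), dim = dim(cnt))) * scale  # -> L x T
  clab <- vapply(vars$nfo$clab, as.character, "")
  pos <- as.numeric(vars$mrk$pos)
  y <- as.numeric(vars$mrk$y)
  label <- if (layout == "iv_i") {
    ifelse(is.nan(y) | is.na(y), NA_integer_,
           ifelse(y < 0, 1L, 2L))
  } else {
    ifelse(is.nan(y) | is.na(y), NA_integer_, as.integer(y))
  }
  continuous_eeg(data, fs = as.numeric(vars$nfo$fs), channel_names = clab,
                 events = data.frame(sample = as.integer(pos - 1),
                                     label = label))
}
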