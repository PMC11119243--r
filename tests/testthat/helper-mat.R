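# Minimal MAT v5 *writer* used to fabricate competition-style fixtures in
# tests. Kept independent of the package's reader (separate code path,
# written from the format description), so writer/reader round-trips are a
# meaningful check.

mat5_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

mat5_element <- function(type, payload) {
  pad <- (8L - (length(payload) %% 8L)) %% 8L
  c(mat5_u32(type), mat5_u32(length(payload)), payload, raw(pad))
}

# Full miMATRIX element. `data_raw` is the pre-assembled class-specific
# subelement stream.
mat5_array <- function(name, mx_class, dims, data_raw) {
  flags <- c(mat5_u32(mx_class), mat5_u32(0))
  payload <- c(
    mat5_element(6L, flags),                                   # miUINT32
    mat5_element(5L, do.call(c, lapply(dims, mat5_u32))),      # miINT32 dims
    mat5_element(1L, charToRaw(name)),                         # miINT8 name
    data_raw)
  mat5_element(14L, payload)
}

mat5_double <- function(name, m) {
  m <- as.matrix(m)
  mat5_array(name, 6L, dim(m),
             mat5_element(9L, writeBin(as.numeric(m), raw(), size = 8,
                                       endian = "little")))
}

mat5_int16 <- function(name, m) {
  m <- as.matrix(m)
  mat5_array(name, 10L, dim(m),
             mat5_element(3L, writeBin(as.integer(m), raw(), size = 2,
                                       endian = "little")))
}

mat5_char <- function(name, s) {
  bytes <- charToRaw(s)
  mat5_array(name, 4L, c(1L, length(bytes)), mat5_element(16L, bytes))
}

mat5_cell_strings <- function(name, strs) {
  inner <- do.call(c, lapply(strs, function(s) mat5_char("", s)))
  mat5_array(name, 1L, c(1L, length(strs)), inner)
}

# 1x1 struct; fields is a named list of raw miMATRIX elements built with
# the helpers above (their names are ignored inside a struct).
mat5_struct <- function(name, fields) {
  fnames <- names(fields)
  name_len <- 32L
  fn_raw <- do.call(c, lapply(fnames, function(f) {
    b <- charToRaw(f)
    c(b, raw(name_len - length(b)))
  }))
  payload <- c(
    mat5_element(5L, mat5_u32(name_len)),
    mat5_element(1L, fn_raw),
    do.call(c, unname(fields)))
  mat5_array(name, 2L, c(1L, 1L), payload)
}

mat5_write <- function(path, elements) {
  desc <- charToRaw(sprintf("MATLAB 5.0 MAT-file, written by micsel tests"))
  header <- c(desc, raw(116L - length(desc)), raw(8L),
              as.raw(c(0x00, 0x01)), charToRaw("IM"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(header, con)
  for (el in elements) writeBin(el, con)
  invisible(path)
}

# Competition-style fixture: continuous int16 signal, marker struct and
# info struct. `y` may contain NaN for unlabeled markers.
write_bci_fixture <- function(path, cnt, pos, y, clab, fs = 100) {
  mat5_write(path, list(
    mat5_int16("cnt", cnt),
    mat5_struct("mrk", list(pos = mat5_double("", matrix(pos, 1)),
                            y = mat5_double("", matrix(y, 1)))),
    mat5_struct("nfo", list(fs = mat5_double("", matrix(fs)),
                            clab = mat5_cell_strings("", clab)))))
}
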