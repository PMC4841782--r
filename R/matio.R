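#' Minimal MAT v5 file reader and writer
#'
#' Self-contained support for the subset of the MATLAB level-5 binary
#' format needed to exchange behavioral source data: numeric arrays
#' (stored as any integer/float type), character arrays, cell arrays and
#' structs, plus zlib-compressed elements. The writer emits uncompressed
#' little-endian files with double, character and cell-of-double
#' variables, sufficient to round-trip per-fish turn-angle tables.
#'
#' @name matio
NULL

mat_type_info <- function(type) {
  switch(as.character(type),
    "1" = list(what = "integer", size = 1L, signed = TRUE),   # miINT8
    "2" = list(what = "integer", size = 1L, signed = FALSE),  # miUINT8
    "3" = list(what = "integer", size = 2L, signed = TRUE),   # miINT16
    "4" = list(what = "integer", size = 2L, signed = FALSE),  # miUINT16
    "5" = list(what = "integer", size = 4L, signed = TRUE),   # miINT32
    "6" = list(what = "integer", size = 4L, signed = FALSE),  # miUINT32
    "7" = list(what = "numeric", size = 4L, signed = TRUE),   # miSINGLE
    "9" = list(what = "numeric", size = 8L, signed = TRUE),   # miDOUBLE
    "16" = list(what = "integer", size = 1L, signed = FALSE), # miUTF8
    stop("unsupported MAT data type: ", type, call. = FALSE)
  )
}

# read one tag+data subelement from a raw cursor; returns value + new offset
mat_read_subelement <- function(bytes, off, endian) {
  word <- readBin(bytes[off + 1:4], "integer", 1, 4, endian = endian)
  small_size <- bitwAnd(bitwShiftR(word, 16L), 0xFFFFL)
  if (small_size != 0L) {
    type <- bitwAnd(word, 0xFFFFL)
    size <- small_size
    data <- bytes[off + 4 + seq_len(size)]
    off <- off + 8L
  } else {
    type <- word
    size <- readBin(bytes[off + 5:8], "integer", 1, 4, endian = endian)
    data <- if (size > 0) bytes[off + 8 + seq_len(size)] else raw(0)
    # data padded to 8 bytes, except for compressed (miCOMPRESSED) elements
    pad <- if (type == 15L) 0L else (-size %% 8L)
    off <- off + 8L + size + pad
  }
  list(type = type, size = size, data = data, off = off)
}

mat_decode_numeric <- function(sub, endian) {
  info <- mat_type_info(sub$type)
  n <- sub$size / info$size
  vals <- readBin(sub$data, info$what, n, info$size, signed = info$signed,
                  endian = endian)
  if (sub$type %in% c(4, 6) && info$size >= 2) {
    vals[vals < 0] <- vals[vals < 0] + 2^(8 * info$size)
  }
  as.numeric(vals)
}

# parse one miMATRIX payload into an R object (named via attr "mat_name")
mat_parse_matrix <- function(bytes, endian) {
  off <- 0L
  flags <- mat_read_subelement(bytes, off, endian); off <- flags$off
  class_id <- as.integer(bitwAnd(readBin(flags$data[1:4], "integer", 1, 4,
                                         endian = endian), 0xFFL))
  dims_sub <- mat_read_subelement(bytes, off, endian); off <- dims_sub$off
  dims <- readBin(dims_sub$data, "integer", dims_sub$size / 4, 4,
                  endian = endian)
  name_sub <- mat_read_subelement(bytes, off, endian); off <- name_sub$off
  nm <- rawToChar(name_sub$data[name_sub$data != as.raw(0)])
  value <- if (class_id %in% 6:15) { # numeric classes incl. logical-ish
    re <- mat_read_subelement(bytes, off, endian); off <- re$off
    v <- mat_decode_numeric(re, endian)
    if (length(dims) > 1 && prod(dims) == length(v)) {
      array(v, dim = dims)
    } else v
  } else if (class_id == 4) { # char
    ch <- mat_read_subelement(bytes, off, endian); off <- ch$off
    codes <- mat_decode_numeric(ch, endian)
    intToUtf8(codes[codes > 0])
  } else if (class_id == 1) { # cell
    n_cells <- prod(dims)
    out <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      el <- mat_read_subelement(bytes, off, endian)
      off <- el$off
      if (el$type != 14) stop("malformed cell array", call. = FALSE)
      child <- mat_parse_matrix(el$data, endian)
      attr(child, "mat_name") <- NULL
      out[[i]] <- child
    }
    out
  } else if (class_id == 2) { # struct
    fl_sub <- mat_read_subelement(bytes, off, endian); off <- fl_sub$off
    flen <- readBin(fl_sub$data, "integer", 1, 4, endian = endian)
    fn_sub <- mat_read_subelement(bytes, off, endian); off <- fn_sub$off
    n_fields <- fn_sub$size / flen
    f_names <- vapply(seq_len(n_fields), function(i) {
      b <- fn_sub$data[(i - 1) * flen + seq_len(flen)]
      rawToChar(b[b != as.raw(0)])
    }, character(1))
    out <- stats::setNames(vector("list", n_fields), f_names)
    for (i in seq_len(n_fields)) {
      el <- mat_read_subelement(bytes, off, endian)
      off <- el$off
      child <- mat_parse_matrix(el$data, endian)
      attr(child, "mat_name") <- NULL
      out[[i]] <- child
    }
    out
  } else {
    structure(list(), class_id = class_id, unsupported = TRUE)
  }
  attr(value, "mat_name") <- nm
  value
}

#' Read a MAT v5 file
#'
#' @param path Path to a `.mat` file (level-5 format; v7.3/HDF5 files are
#'   rejected).
#' @return Named list of variables (numeric arrays, strings, lists for
#'   cells, named lists for structs).
#' @export
read_mat <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  if (length(bytes) < 128) stop("not a MAT v5 file (truncated header)", call. = FALSE)
  magic <- rawToChar(bytes[127:128])
  endian <- if (magic == "IM") "little" else if (magic == "MI") "big" else
    stop("not a MAT v5 file (bad endian marker); v7.3 files are not supported",
         call. = FALSE)
  off <- 128L
  out <- list()
  while (off + 8 <= length(bytes)) {
    el <- mat_read_subelement(bytes, off, endian)
    off <- el$off
    payload <- el$data
    type <- el$type
    if (type == 15) { # miCOMPRESSED: zlib stream
      payload <- memDecompress(payload, type = "gzip")
      word <- readBin(payload[1:4], "integer", 1, 4, endian = endian)
      type <- bitwAnd(word, 0xFFFFL)
      payload <- payload[-(1:8)]
    }
    if (type != 14) next # skip non-matrix top-level elements
    val <- mat_parse_matrix(payload, endian)
    nm <- attr(val, "mat_name")
    attr(val, "mat_name") <- NULL
    out[[nm]] <- val
  }
  out
}

mat_tag <- function(type, size) {
  c(writeBin(as.integer(type), raw(), 4, endian = "little"),
    writeBin(as.integer(size), raw(), 4, endian = "little"))
}

mat_pad <- function(bytes) {
  c(bytes, raw(-length(bytes) %% 8))
}

mat_encode_matrix <- function(x, name) {
  if (is.list(x)) {
    class_id <- 1L
    dims <- c(length(x), 1L)
    data <- raw(0)
    for (el in x) {
      child <- mat_encode_matrix(el, "")
      data <- c(data, child)
    }
    data_sub <- data
  } else if (is.character(x)) {
    class_id <- 4L
    codes <- utf8ToInt(x)
    dims <- c(1L, length(codes))
    payload <- writeBin(as.integer(codes), raw(), 2, endian = "little")
    data_sub <- c(mat_tag(4, length(payload)), mat_pad(payload))
  } else {
    class_id <- 6L # mxDOUBLE_CLASS
    v <- as.numeric(x)
    dims <- if (is.null(dim(x))) c(length(v), 1L) else dim(x)
    payload <- writeBin(v, raw(), 8, endian = "little")
    data_sub <- c(mat_tag(9, length(payload)), mat_pad(payload))
  }
  flags <- c(mat_tag(6, 8),
             writeBin(as.integer(class_id), raw(), 4, endian = "little"),
             raw(4))
  dims_raw <- writeBin(as.integer(dims), raw(), 4, endian = "little")
  dims_sub <- c(mat_tag(5, length(dims_raw)), mat_pad(dims_raw))
  name_raw <- charToRaw(name)
  name_sub <- c(mat_tag(1, length(name_raw)), mat_pad(name_raw))
  body <- c(flags, dims_sub, name_sub, data_sub)
  c(mat_tag(14, length(body)), body)
}

#' Write variables to a MAT v5 file
#'
#' Uncompressed little-endian level-5 output. Supported values: numeric
#' vectors/matrices (written as doubles), single strings, and unnamed
#' lists of numerics (written as cell arrays).
#'
#' @param vars Named list of variables.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mat <- function(vars, path) {
  if (is.null(names(vars)) || any(names(vars) == "")) {
    stop("all variables must be named", call. = FALSE)
  }
  desc <- sprintf("MATLAB 5.0 MAT-file, written by slalom on %s",
                  format(Sys.time(), "%Y-%m-%d"))
  header <- charToRaw(desc)
  header <- c(header, charToRaw(strrep(" ", 116 - length(header))))
  header <- c(header, raw(8)) # subsystem offset
  header <- c(header, writeBin(c(0x00L, 0x01L), raw(), 1)) # version 0x0100 LE
  header <- c(header, charToRaw("IM"))
  body <- raw(0)
  for (nm in names(vars)) {
    body <- c(body, mat_encode_matrix(vars[[nm]], nm))
  }
  writeBin(c(header, body), path)
  invisible(path)
}
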