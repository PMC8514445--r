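# Minimal MAT-file (Level 5) support: enough to export ROI masks as named
# uint8 arrays readable by MATLAB / scipy.io.loadmat, and to read such files
# back. Only 2D uint8/int32/double numeric arrays are handled.

mat5_pad <- function(n) (8 - n %% 8) %% 8

# One miMATRIX element for a 2D integer/numeric matrix.
mat5_matrix_element <- function(name, m) {
  h <- nrow(m); w <- ncol(m)
  is_int <- is.integer(m) && all(m >= 0) && all(m <= 255)
  if (is_int) {
    mx_class <- 9L; mi_type <- 2L; elsize <- 1L   # mxUINT8_CLASS / miUINT8
    data_raw <- as.raw(as.vector(m))
  } else {
    mx_class <- 6L; mi_type <- 9L; elsize <- 8L   # mxDOUBLE_CLASS / miDOUBLE
    data_raw <- writeBin(as.numeric(as.vector(m)), raw(), size = 8,
                         endian = "little")
  }
  u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
  i32 <- u32
  flags <- c(u32(6L), u32(8L), u32(mx_class), u32(0L))
  dims <- c(u32(5L), u32(8L), i32(h), i32(w))
  nm <- charToRaw(name)
  name_el <- c(u32(1L), u32(length(nm)), nm, raw(mat5_pad(length(nm))))
  nbytes_data <- length(data_raw)
  data_el <- c(u32(mi_type), u32(nbytes_data), data_raw,
               raw(mat5_pad(nbytes_data)))
  body <- c(flags, dims, name_el, data_el)
  c(u32(14L), u32(length(body)), body)
}

#' Write named matrices to a MAT-file (Level 5)
#'
#' Integer matrices with values in 0..255 are stored as uint8 arrays (the
#' form used for ROI masks); other numeric matrices as double arrays.
#'
#' @param arrays named list of matrices.
#' @param path output `.mat` path.
#' @return `path`, invisibly.
#' @export
write_mat5 <- function(arrays, path) {
  stopifnot(length(names(arrays)) == length(arrays), all(names(arrays) != ""))
  header <- charToRaw(sprintf(
    "MATLAB 5.0 MAT-file, created by mesomap on %s", format(Sys.Date())))
  header <- c(header, raw(116 - length(header)))
  header[header == as.raw(0)] <- charToRaw(" ")
  subsys <- raw(8)
  version <- writeBin(c(0x00L, 0x01L), raw(), size = 1)  # 0x0100 little-endian
  endian <- charToRaw("IM")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, subsys, version, endian), con)
  for (nm in names(arrays)) {
    writeBin(mat5_matrix_element(nm, arrays[[nm]]), con)
  }
  invisible(path)
}

#' Read a MAT-file (Level 5) written by [write_mat5()]
#'
#' Supports uncompressed 2D uint8 / int32 / double arrays.
#'
#' @param path `.mat` path.
#' @return named list of matrices.
#' @export
read_mat5 <- function(path) {
  raw_all <- readBin(path, "raw", n = file.size(path))
  if (rawToChar(raw_all[127:128]) != "IM") {
    stop("unsupported MAT-file endianness or format")
  }
  u32 <- function(off) {
    readBin(raw_all[(off + 1):(off + 4)], "integer", size = 4,
            endian = "little")
  }
  out <- list()
  pos <- 128L
  while (pos + 8 <= length(raw_all)) {
    el_type <- u32(pos); el_bytes <- u32(pos + 4L)
    if (el_type != 14L) stop("unsupported top-level MAT element type ", el_type)
    p <- pos + 8L
    # array flags
    stopifnot(u32(p) == 6L)
    p <- p + 16L
    # dimensions
    stopifnot(u32(p) == 5L)
    ndim <- u32(p + 4L) / 4L
    dims <- vapply(seq_len(ndim), function(i) u32(p + 4L + 4L * i), integer(1))
    p <- p + 8L + 4L * ndim + mat5_pad(4L * ndim)
    # name (may be packed in a small-element tag)
    t1 <- u32(p)
    if (bitwAnd(t1, bitwShiftL(65535L, 16L)) != 0L) {
      nlen <- bitwShiftR(t1, 16L)
      name <- rawToChar(raw_all[(p + 5L):(p + 4L + nlen)])
      p <- p + 8L
    } else {
      nlen <- u32(p + 4L)
      name <- rawToChar(raw_all[(p + 9L):(p + 8L + nlen)])
      p <- p + 8L + nlen + mat5_pad(nlen)
    }
    # data
    dtype <- u32(p); dbytes <- u32(p + 4L)
    dat <- raw_all[(p + 9L):(p + 8L + dbytes)]
    vals <- switch(as.character(dtype),
      "2" = as.integer(dat),
      "5" = readBin(dat, "integer", n = dbytes / 4, size = 4,
                    endian = "little"),
      "9" = readBin(dat, "double", n = dbytes / 8, size = 8,
                    endian = "little"),
      stop("unsupported MAT data type ", dtype))
    out[[name]] <- matrix(vals, dims[1], dims[2])
    pos <- pos + 8L + el_bytes
  }
  out
}
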