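#' Minimal NPY (v1.0) reader/writer for 3-D float64 arrays
#'
#' The pipeline persists every intermediate stack as a NumPy `.npy` file
#' (little-endian float64, C order, 3-D shape `(n_frames, height, width)`),
#' so processed data can be inspected with any NumPy-aware tool. Only the
#' subset of the format the pipeline emits is supported on read:
#' `<f8` data in either C or Fortran order, 1-3 dimensions.
#'
#' @param path file path ending in `.npy`.
#' @param x numeric array (1-3 dimensions); `NaN` entries (undefined pixels)
#'   are preserved bit-exactly.
#' @return `write_npy()` returns `path` invisibly; `read_npy()` returns the
#'   array with its original dimensions.
#' @keywords internal
#' @name npy
NULL

NPY_MAGIC <- as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59))

#' @rdname npy
write_npy <- function(x, path) {
  if (!is.numeric(x)) stop("write_npy: numeric data required")
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  if (length(d) > 3L) stop("write_npy: at most 3 dimensions supported")
  # C-order flat sequence: last index varies fastest
  flat <- if (length(d) > 1L) as.vector(aperm(array(x, dim = d), rev(seq_along(d)))) else as.vector(x)
  shape_str <- if (length(d) == 1L) sprintf("(%d,)", d) else
    sprintf("(%s)", paste(d, collapse = ", "))
  header <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': %s, }",
                    shape_str)
  # pad so that total preamble (10 bytes) + header is a multiple of 64
  pad <- 64L - ((10L + nchar(header) + 1L) %% 64L)
  if (pad == 64L) pad <- 0L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(NPY_MAGIC, con)
  writeBin(as.raw(c(1L, 0L)), con)                      # version 1.0
  writeBin(as.integer(nchar(header)), con, size = 2L,
           endian = "little")
  writeChar(header, con, eos = NULL)
  writeBin(as.vector(flat), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname npy
read_npy <- function(path) {
  if (!file.exists(path)) stop("read_npy: no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readBin(con, "raw", n = 6L)
  if (length(magic) < 6L || !identical(magic, NPY_MAGIC))
    stop("read_npy: not an NPY file (bad magic): ", path)
  ver <- readBin(con, "raw", n = 2L)
  if (length(ver) < 2L || ver[1] != as.raw(1L))
    stop("read_npy: unsupported NPY version in ", path)
  hlen <- readBin(con, "integer", n = 1L, size = 2L, signed = FALSE,
                  endian = "little")
  if (length(hlen) < 1L) stop("read_npy: truncated header in ", path)
  header <- readChar(con, hlen, useBytes = TRUE)
  if (nchar(header) < hlen) stop("read_npy: truncated header in ", path)
  descr <- sub(".*'descr'\\s*:\\s*'([^']+)'.*", "\\1", header)
  if (!descr %in% c("<f8")) stop("read_npy: unsupported dtype '", descr,
                                 "' in ", path, " (only <f8 is supported)")
  fortran <- grepl("'fortran_order'\\s*:\\s*True", header)
  shape_s <- sub(".*'shape'\\s*:\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shape_s), ",")[[1]])
  shape <- shape[!is.na(shape)]
  n <- prod(shape)
  vals <- readBin(con, "double", n = n, size = 8L, endian = "little")
  if (length(vals) < n)
    stop("read_npy: truncated data in ", path, ": expected ", n,
         " values, got ", length(vals))
  if (length(shape) <= 1L) return(vals)
  if (fortran) {
    array(vals, dim = shape)
  } else {
    aperm(array(vals, dim = rev(shape)), rev(seq_along(shape)))
  }
}
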