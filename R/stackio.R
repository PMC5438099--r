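#' Image stack container
#'
#' An `image_stack` holds a widefield recording as a 3-D double array with
#' dimensions `(n_frames, height, width)` plus the acquisition frame rate.
#' Undefined pixels (outside the imaged field, masked, or exposed by
#' resampling) are marked `NaN`; every operation in the package either
#' propagates or explicitly skips them.
#'
#' @param data numeric 3-D array, `n_frames x height x width`. A matrix is
#'   accepted as a single frame.
#' @param fps frame rate in Hz (> 0).
#' @return An object of class `image_stack`.
#' @examples
#' s <- image_stack(array(rnorm(5 * 4 * 6), dim = c(5, 4, 6)), fps = 30)
#' n_frames(s)
#' @export
image_stack <- function(data, fps) {
  if (is.matrix(data)) data <- array(data, dim = c(1L, dim(data)))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("image_stack: data must be a 3-D array (frames x height x width)")
  if (any(dim(data) < 1L)) stop("image_stack: empty dimension")
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop("image_stack: fps must be a single positive number")
  storage.mode(data) <- "double"
  structure(list(data = data, fps = as.numeric(fps)), class = "image_stack")
}

#' @rdname image_stack
#' @param x an `image_stack`.
#' @export
n_frames <- function(x) dim(x$data)[1L]

#' @rdname image_stack
#' @export
frame_dim <- function(x) dim(x$data)[2:3]

#' @rdname image_stack
#' @param i frame index, 0-based (frame 0 is the first recorded frame,
#'   matching on-disk frame numbering).
#' @export
get_frame <- function(x, i) {
  if (i < 0 || i >= n_frames(x)) stop("get_frame: frame index out of range")
  x$data[i + 1L, , ]
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  nundef <- sum(!is.finite(x$data))
  cat(sprintf("<image_stack> %d frames, %d x %d px, %.6g fps (%.1f s)%s\n",
              d[1], d[2], d[3], x$fps, d[1] / x$fps,
              if (nundef > 0) sprintf(", %d undefined values", nundef) else ""))
  invisible(x)
}

# time x pixel matrix view; pixel j = (row, col) with row fastest
# (R's column-major order), so .mat_to_stack inverts it exactly.
.stack_to_mat <- function(stack) {
  d <- dim(stack$data)
  dim(stack$data) <- c(d[1], d[2] * d[3])
  stack$data
}

.mat_to_stack <- function(m, hw, fps) {
  dim(m) <- c(nrow(m), hw[1], hw[2])
  image_stack(m, fps)
}

#' RAW stack layout description
#'
#' Describes a headerless binary recording: frame after frame, each frame a
#' row-major scan of pixels, each pixel `n_channels` interleaved samples
#' (e.g. `R,G,B,R,G,B,...` for RGB 24-bit camera output).
#'
#' @param width,height frame size in pixels.
#' @param n_channels interleaved channels per pixel.
#' @param dtype sample type: one of `"uint8"`, `"float32"`, `"float64"`.
#' @param channel_index 0-based channel to keep on import (the green channel
#'   of an RGB recording is `channel_index = 1`).
#' @return A `raw_spec` list.
#' @export
raw_spec <- function(width, height, n_channels = 1L, dtype = "uint8",
                     channel_index = 0L) {
  dtype <- match.arg(dtype, c("uint8", "float32", "float64"))
  if (channel_index < 0 || channel_index >= n_channels)
    stop("raw_spec: channel_index must be in [0, n_channels)")
  if (width < 1 || height < 1 || n_channels < 1)
    stop("raw_spec: width, height, n_channels must be >= 1")
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_channels = as.integer(n_channels), dtype = dtype,
                 channel_index = as.integer(channel_index)),
            class = "raw_spec")
}

.dtype_bytes <- c(uint8 = 1L, float32 = 4L, float64 = 8L)

#' Read a headerless RAW image stack
#'
#' Imports one channel of a multichannel interleaved RAW recording as a
#' float64 `image_stack`. The number of frames is inferred from the file
#' size; a size that is not an exact multiple of one frame is an error.
#'
#' @param path path to the `.raw` file.
#' @param spec a [raw_spec()] describing the layout.
#' @param fps frame rate in Hz.
#' @return An [image_stack()].
#' @export
read_raw_stack <- function(path, spec, fps) {
  if (!file.exists(path)) stop("read_raw_stack: no such file: ", path)
  stopifnot(inherits(spec, "raw_spec"))
  bytes <- .dtype_bytes[[spec$dtype]]
  fsize <- file.size(path)
  frame_bytes <- as.numeric(spec$width) * spec$height * spec$n_channels * bytes
  if (fsize %% frame_bytes != 0)
    stop(sprintf(
      "read_raw_stack: %s (%d bytes) is not a whole number of %dx%dx%d %s frames (frame = %d bytes, %d residual bytes)",
      path, fsize, spec$width, spec$height, spec$n_channels, spec$dtype,
      frame_bytes, fsize %% frame_bytes))
  nf <- as.integer(fsize / frame_bytes)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  ntot <- nf * spec$width * spec$height * spec$n_channels
  v <- switch(spec$dtype,
    uint8   = as.double(readBin(con, "integer", n = ntot, size = 1L,
                                signed = FALSE)),
    float32 = readBin(con, "double", n = ntot, size = 4L, endian = "little"),
    float64 = readBin(con, "double", n = ntot, size = 8L, endian = "little"))
  if (length(v) < ntot) stop("read_raw_stack: short read from ", path)
  # sample order on disk: channel fastest, then column, row, frame
  ch <- v[seq.int(spec$channel_index + 1L, length(v), by = spec$n_channels)]
  # ch order: column fastest, then row, then frame == C order (nf, h, w)
  arr <- aperm(array(ch, dim = c(spec$width, spec$height, nf)), c(3, 2, 1))
  image_stack(arr, fps)
}

#' Write an image stack as headerless single-channel RAW
#'
#' Companion to [read_raw_stack()]; used by the synthetic-data generator to
#' lay project fixtures on disk. Only single-channel output is produced.
#'
#' @inheritParams read_raw_stack
#' @param stack an [image_stack()].
#' @param dtype sample type to write; `uint8` values are rounded and clipped
#'   to `[0, 255]`.
#' @return `path`, invisibly.
#' @export
write_raw_stack <- function(stack, path, dtype = "float64") {
  dtype <- match.arg(dtype, c("uint8", "float32", "float64"))
  v <- as.vector(aperm(stack$data, c(3, 2, 1)))   # channel-less C order
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  switch(dtype,
    uint8   = writeBin(as.integer(pmin(pmax(round(v), 0), 255)), con,
                       size = 1L),
    float32 = writeBin(v, con, size = 4L, endian = "little"),
    float64 = writeBin(v, con, size = 8L, endian = "little"))
  invisible(path)
}

#' Read a multipage TIFF stack
#'
#' Pages are taken in file order as time. Integer samples are imported at
#' their stored values (no 0-1 rescaling) and converted to float64.
#'
#' @param path path to the TIFF file.
#' @param channel_index 0-based channel to keep when pages carry 2 or more
#'   samples per pixel; must be `NULL` for grayscale input.
#' @param fps frame rate in Hz.
#' @return An [image_stack()].
#' @export
read_tiff_stack <- function(path, channel_index = NULL, fps) {
  if (!file.exists(path)) stop("read_tiff_stack: no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE,
                                   info = TRUE),
                    error = function(e)
                      stop("read_tiff_stack: cannot read ", path, ": ",
                           conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  take <- function(p) {
    # multi-sample integer pages come back rescaled to [0, 1] even with
    # as.is; undo the rescaling so stored values are preserved
    bits <- attr(p, "bits.per.sample")
    if (length(dim(p)) == 3L && is.double(p) && !is.null(bits) &&
          bits %in% c(8L, 16L, 32L) && all(p >= 0 & p <= 1))
      p <- round(p * (2^bits - 1))
    if (length(dim(p)) == 3L) {
      ns <- dim(p)[3]
      if (is.null(channel_index))
        stop("read_tiff_stack: ", ns, "-sample pages need channel_index")
      if (channel_index < 0 || channel_index >= ns)
        stop("read_tiff_stack: channel_index ", channel_index,
             " out of range for ", ns, " samples per pixel")
      p[, , channel_index + 1L]
    } else p
  }
  mats <- lapply(pages, take)
  hw <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) identical(dim(m), hw), logical(1))))
    stop("read_tiff_stack: pages differ in size")
  arr <- array(0, dim = c(length(mats), hw))
  for (i in seq_along(mats)) arr[i, , ] <- mats[[i]]
  image_stack(arr, fps)
}

#' Persist / load an image stack in the native NPY format
#'
#' `persist_stack()` writes the frame data as a 3-D C-order float64 `.npy`
#' file plus a small JSON sidecar (`<path>.json`) holding the frame rate, so
#' the round trip `load_stack(persist_stack(s, p))` reproduces `s`
#' bit-exactly, undefined-pixel markers included.
#'
#' @param stack an [image_stack()].
#' @param path destination `.npy` path.
#' @param fps frame rate override for files without a sidecar.
#' @return `persist_stack()` returns `path` invisibly; `load_stack()` an
#'   [image_stack()].
#' @export
persist_stack <- function(stack, path) {
  tryCatch({
    write_npy(stack$data, path)
    jsonlite::write_json(list(fps = stack$fps), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }, error = function(e)
    stop("persist_stack: cannot write ", path, ": ", conditionMessage(e)))
  invisible(path)
}

#' @rdname persist_stack
#' @export
load_stack <- function(path, fps = NULL) {
  arr <- read_npy(path)
  if (length(dim(arr)) != 3L)
    stop("load_stack: ", path, " is not a 3-D stack")
  side <- paste0(path, ".json")
  if (is.null(fps)) {
    if (!file.exists(side))
      stop("load_stack: no fps sidecar for ", path, "; pass fps explicitly")
    fps <- jsonlite::read_json(side)$fps
  }
  image_stack(arr, fps)
}
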