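#' Zero-lag Pearson correlation of two series
#'
#' Frames where either series is undefined are dropped pairwise before the
#' coefficient is computed; the effective sample size is attached as
#' attribute `"n"`. A constant series has no defined correlation and
#' returns `NA` with a warning.
#'
#' @param a,b equal-length numeric series (>= 3 defined pairs).
#' @return The correlation coefficient in `[-1, 1]`, with attribute `n`.
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) stop("pearson_r: lengths differ")
  ok <- is.finite(a) & is.finite(b)
  n <- sum(ok)
  if (n < 3L) stop("pearson_r: fewer than 3 defined pairs")
  a <- a[ok] - mean(a[ok]); b <- b[ok] - mean(b[ok])
  sa <- sqrt(sum(a * a)); sb <- sqrt(sum(b * b))
  if (sa == 0 || sb == 0) {
    warning("pearson_r: constant series, correlation undefined")
    return(structure(NA_real_, n = n))
  }
  structure(max(-1, min(1, sum(a * b) / (sa * sb))), n = n)
}

#' Mean time course over a set of pixels
#'
#' @param stack an [image_stack()].
#' @param pixels integer n x 2 matrix of 0-based `(x_px, y_px)` coordinates
#'   (as returned by [seed_pixels()]).
#' @return Numeric vector: per-frame mean over the set's defined pixels.
#' @export
roi_timecourse <- function(stack, pixels) {
  if (is.null(dim(pixels))) pixels <- matrix(pixels, ncol = 2)
  d <- frame_dim(stack)
  if (any(pixels[, 1] < 0 | pixels[, 1] >= d[2] |
            pixels[, 2] < 0 | pixels[, 2] >= d[1]))
    stop("roi_timecourse: pixel outside the image")
  m <- .stack_to_mat(stack)
  cols <- pixels[, 2] + 1L + d[1] * pixels[, 1]
  sub <- m[, cols, drop = FALSE]
  if (all(!is.finite(sub))) stop("roi_timecourse: RoI is fully undefined")
  rowMeans(sub, na.rm = TRUE)
}

#' Seed-pixel correlation map
#'
#' Zero-lag Pearson correlation between the seed pixel's time series and
#' every other pixel's, over the full (typically concatenated) series.
#' Masked or constant pixels are undefined in the map; the value at the
#' seed itself is 1.
#'
#' @param stack an [image_stack()].
#' @param seed 0-based `(x_px, y_px)` seed coordinate; must be defined and
#'   nonconstant.
#' @param provenance optional character vector recording the manipulation
#'   history of the source stack (carried into the result for labelling).
#' @return An object of class `spc_map`: list with `values`
#'   (height x width matrix of r), `seed`, and `provenance`.
#' @export
spc_map <- function(stack, seed, provenance = character()) {
  d <- frame_dim(stack)
  if (seed[1] < 0 || seed[1] >= d[2] || seed[2] < 0 || seed[2] >= d[1])
    stop("spc_map: seed outside the image")
  m <- .stack_to_mat(stack)
  scol <- seed[2] + 1L + d[1] * seed[1]
  s <- m[, scol]
  if (!all(is.finite(s)))
    stop("spc_map: seed pixel is in a masked/undefined region")
  if (stats::sd(s) == 0) stop("spc_map: seed series is constant")
  nt <- nrow(m)
  full <- colSums(is.finite(m)) == nt
  vals <- rep(NaN, ncol(m))
  # fully defined pixels: one standardised cross-product
  z <- m[, full, drop = FALSE]
  z <- sweep(z, 2L, colMeans(z))
  ss <- sqrt(colSums(z * z))
  sz <- s - mean(s)
  r <- as.vector(crossprod(sz, z)) / (sqrt(sum(sz * sz)) * ss)
  r[ss == 0] <- NaN
  vals[full] <- pmax(-1, pmin(1, r))          # guard floating round-off
  # partially defined pixels: pairwise-complete fallback
  part <- which(!full & colSums(is.finite(m)) >= 3L)
  for (j in part)
    vals[j] <- suppressWarnings(as.numeric(pearson_r(s, m[, j])))
  structure(list(values = matrix(vals, d[1], d[2]),
                 seed = as.numeric(seed),
                 provenance = provenance),
            class = "spc_map")
}

#' @export
print.spc_map <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<spc_map> seed (%g, %g) px; %d defined pixels; r in [%.3f, %.3f]\n",
              x$seed[1], x$seed[2], length(v), min(v), max(v)))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' Cross-trial RoI correlation matrices
#'
#' For every stack (trial), the zero-lag Pearson correlation is computed
#' between the time courses of every RoI pair; the result reports the mean
#' across trials and the sample (n-1) standard deviation showing how the
#' coefficient varies across trials.
#'
#' @param stacks list of [image_stack()]s (one per trial).
#' @param rois RoI data frame from [import_roi_csv()] (columns `name`,
#'   `length`, `x`, `y` in microns); at least 2 rows.
#' @param cs a [coordinate_system()].
#' @return An object of class `correlation_matrices`: `roi_names`, `mean_r`
#'   (symmetric, unit diagonal), `std_r` (symmetric, zero diagonal, all
#'   zero when `n_stacks = 1`), `n_stacks`.
#' @export
correlation_matrix <- function(stacks, rois, cs) {
  if (length(stacks) < 1L) stop("correlation_matrix: no stacks")
  if (nrow(rois) < 2L) stop("correlation_matrix: at least 2 RoIs required")
  k <- nrow(rois)
  rmats <- array(NA_real_, dim = c(k, k, length(stacks)))
  for (si in seq_along(stacks)) {
    st <- stacks[[si]]
    tc <- matrix(0, n_frames(st), k)
    for (ri in seq_len(k)) {
      px <- seed_pixels(rois[ri, ], cs, frame_dim(st))
      tc[, ri] <- tryCatch(roi_timecourse(st, px), error = function(e)
        stop(sprintf("correlation_matrix: RoI '%s' unusable in stack %d: %s",
                     rois$name[ri], si, conditionMessage(e))))
    }
    rm <- diag(1, k)
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      rij <- pearson_r(tc[, i], tc[, j])
      rm[i, j] <- rm[j, i] <- as.numeric(rij)
    }
    rmats[, , si] <- rm
  }
  mean_r <- apply(rmats, c(1, 2), mean)
  std_r <- if (length(stacks) == 1L) matrix(0, k, k) else
    apply(rmats, c(1, 2), stats::sd)
  diag(std_r) <- 0
  structure(list(roi_names = rois$name, mean_r = mean_r, std_r = std_r,
                 n_stacks = length(stacks)),
            class = "correlation_matrices")
}

#' @export
print.correlation_matrices <- function(x, digits = 3, ...) {
  cat(sprintf("<correlation_matrices> %d RoIs x %d stack(s)\nmean r:\n",
              length(x$roi_names), x$n_stacks))
  m <- round(x$mean_r, digits)
  dimnames(m) <- list(x$roi_names, x$roi_names)
  print(m)
  invisible(x)
}

# values in [-1, 1] -> blue-white-red RGB array, NaN -> black
.diverging_rgb <- function(values) {
  pal <- grDevices::colorRamp(c("#2166AC", "#FFFFFF", "#B2182B"))
  v <- (pmax(pmin(values, 1), -1) + 1) / 2
  bad <- !is.finite(v)
  v[bad] <- 0.5
  rgb <- pal(as.vector(v)) / 255
  out <- array(0, dim = c(nrow(values), ncol(values), 3))
  for (ch in 1:3) {
    plane <- matrix(rgb[, ch], nrow(values))
    plane[bad] <- 0
    out[, , ch] <- plane
  }
  out
}

#' Render a correlation map to PNG
#'
#' Symmetric diverging colormap centred at r = 0 (blue negative, red
#' positive); undefined pixels render black.
#'
#' @param x an `spc_map` or a numeric matrix of correlations.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
save_map_png <- function(x, path) {
  values <- if (inherits(x, "spc_map")) x$values else x
  png::writePNG(.diverging_rgb(values), path)
  invisible(path)
}

#' @export
plot.spc_map <- function(x, ...) {
  v <- x$values
  graphics::image(t(v)[, nrow(v):1], zlim = c(-1, 1),
                  col = grDevices::hcl.colors(101, "Blue-Red 2"),
                  axes = FALSE, asp = nrow(v) / ncol(v),
                  main = sprintf("SPC map, seed (%g, %g)", x$seed[1], x$seed[2]),
                  ...)
  invisible(x)
}

#' @export
plot.correlation_matrices <- function(x, ...) {
  k <- length(x$roi_names)
  graphics::image(1:k, 1:k, t(x$mean_r[k:1, ]), zlim = c(-1, 1),
                  col = grDevices::hcl.colors(101, "Blue-Red 2"),
                  axes = FALSE, xlab = "", ylab = "",
                  main = sprintf("mean r across %d stack(s)", x$n_stacks), ...)
  graphics::axis(1, at = 1:k, labels = x$roi_names, las = 2, cex.axis = 0.7)
  graphics::axis(2, at = 1:k, labels = rev(x$roi_names), las = 2,
                 cex.axis = 0.7)
  invisible(x)
}
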