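#' Rigid transform (translation, rotation, scale)
#'
#' The forward map acts on 0-based pixel coordinates `p = (x, y)` about the
#' frame centre `c`: `M(p) = scale * R(theta) (p - c) + c + (dx, dy)`, with
#' `R` rotating counter-clockwise for positive `theta` in the `(x right,
#' y down)` pixel frame. [apply_transform()] moves image content by `M`, so
#' a pure `(1, 0)` shift moves a feature one column to the right.
#'
#' @param dx,dy translation in pixels.
#' @param theta rotation in degrees.
#' @param scale isotropic scale factor (> 0).
#' @return A `rigid_transform` list.
#' @export
rigid_transform <- function(dx = 0, dy = 0, theta = 0, scale = 1) {
  if (scale <= 0) stop("rigid_transform: scale must be > 0")
  structure(list(dx = as.numeric(dx), dy = as.numeric(dy),
                 theta = as.numeric(theta), scale = as.numeric(scale)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> dx=%.3f px, dy=%.3f px, theta=%.3f deg, scale=%.4f\n",
              x$dx, x$dy, x$theta, x$scale))
  invisible(x)
}

#' @rdname rigid_transform
#' @param t a `rigid_transform`.
#' @export
invert_transform <- function(t) {
  th <- -t$theta * pi / 180
  s <- 1 / t$scale
  # d' = -(1/s) R(-theta) d
  dx <- -s * (cos(th) * t$dx - sin(th) * t$dy)
  dy <- -s * (sin(th) * t$dx + cos(th) * t$dy)
  rigid_transform(dx, dy, -t$theta, s)
}

# inverse-map source coordinates for every output pixel of an H x W frame
.transform_coords <- function(h, w, t) {
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  qx <- matrix(rep(0:(w - 1), each = h), h, w)
  qy <- matrix(rep(0:(h - 1), times = w), h, w)
  th <- t$theta * pi / 180
  ux <- (qx - t$dx) - cx
  uy <- (qy - t$dy) - cy
  sx <- (cos(th) * ux + sin(th) * uy) / t$scale + cx
  sy <- (-sin(th) * ux + cos(th) * uy) / t$scale + cy
  list(sx = sx, sy = sy)
}

# bilinear gather; out-of-frame or NaN sources with positive weight -> NaN
.resample_frame <- function(frame, co) {
  h <- nrow(frame); w <- ncol(frame)
  x0 <- floor(co$sx); y0 <- floor(co$sy)
  fx <- co$sx - x0; fy <- co$sy - y0
  gather <- function(xi, yi) {
    ok <- xi >= 0 & xi < w & yi >= 0 & yi < h
    v <- rep(NaN, length(xi))
    v[ok] <- frame[cbind(yi[ok] + 1L, xi[ok] + 1L)]
    v
  }
  wsum <- function(wt, v) ifelse(wt > 0, wt * v, 0)
  x0v <- as.vector(x0); y0v <- as.vector(y0)
  fxv <- as.vector(fx); fyv <- as.vector(fy)
  out <- wsum((1 - fxv) * (1 - fyv), gather(x0v, y0v)) +
    wsum(fxv * (1 - fyv), gather(x0v + 1L, y0v)) +
    wsum((1 - fxv) * fyv, gather(x0v, y0v + 1L)) +
    wsum(fxv * fyv, gather(x0v + 1L, y0v + 1L))
  matrix(out, h, w)
}

#' Apply a rigid transform to every frame of a stack
#'
#' All frames receive the identical transform (movement within a stack is
#' assumed negligible). Resampling is bilinear; pixels mapped from outside
#' the source frame become undefined (`NaN`), never zero, so downstream
#' cropping and correlation can skip them honestly. The identity transform
#' returns the stack bit-exactly.
#'
#' @param stack an [image_stack()] (a bare matrix is treated as one frame).
#' @param t a [rigid_transform()].
#' @return The transformed stack (or matrix, if a matrix was given).
#' @export
apply_transform <- function(stack, t) {
  if (is.matrix(stack)) {
    co <- .transform_coords(nrow(stack), ncol(stack), t)
    return(.resample_frame(stack, co))
  }
  if (t$dx == 0 && t$dy == 0 && t$theta == 0 && t$scale == 1) return(stack)
  d <- frame_dim(stack)
  co <- .transform_coords(d[1], d[2], t)
  out <- stack$data
  for (i in seq_len(n_frames(stack)))
    out[i, , ] <- .resample_frame(stack$data[i, , ], co)
  image_stack(out, stack$fps)
}

# separable zero-padded convolution of a matrix with a 1-D kernel
.conv_sep <- function(m, k) {
  r <- (length(k) - 1L) / 2L
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(0, h + 2 * r, w + 2 * r)
  pad[(r + 1):(r + h), (r + 1):(r + w)] <- m
  a <- stats::filter(pad, k, sides = 2)                 # down columns
  a <- t(stats::filter(t(a), k, sides = 2))             # along rows
  matrix(a[(r + 1):(r + h), (r + 1):(r + w)], h, w)
}

# NaN-aware Gaussian blur: normalised convolution over defined pixels,
# original NaN positions restored
.gaussian_blur <- function(frame, kernel_size) {
  r <- max(1L, floor(kernel_size / 2))
  sigma <- kernel_size / 2
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  bad <- !is.finite(frame)
  f0 <- frame; f0[bad] <- 0
  wm <- matrix(as.numeric(!bad), nrow(frame))
  num <- .conv_sep(f0, k)
  den <- .conv_sep(wm, k)
  out <- num / pmax(den, .Machine$double.eps)
  out[bad] <- NaN
  out
}

#' Unsharp-mask a stack to emphasise blood vessels
#'
#' Per frame, `out = frame + (frame - blur(frame, kernel_size))`, i.e. a
#' unit-amount unsharp mask over a Gaussian blur of standard deviation
#' `kernel_size / 2`. Dark vessels gain contrast against diffuse
#' fluorescence, which is what the registration reference needs.
#' Undefined pixels propagate.
#'
#' @param stack an [image_stack()].
#' @param kernel_size blur kernel size in pixels (>= 1); 8 is the value
#'   used for vessel emphasis on 256 x 256 recordings.
#' @return The sharpened [image_stack()].
#' @export
unsharp_filter <- function(stack, kernel_size) {
  if (!is.numeric(kernel_size) || kernel_size < 1)
    stop("unsharp_filter: kernel_size must be >= 1")
  out <- stack$data
  for (i in seq_len(n_frames(stack))) {
    f <- stack$data[i, , ]
    out[i, , ] <- 2 * f - .gaussian_blur(f, kernel_size)
  }
  image_stack(out, stack$fps)
}

#' Average a frame range into the registration reference
#'
#' Pixelwise mean of the half-open, 0-based frame range `[start_frame,
#' end_frame)`; averaging e.g. frames 400-500 of a sharpened stack
#' emphasises stable vasculature and de-emphasises transient activity.
#'
#' @param stack an [image_stack()].
#' @param start_frame,end_frame 0-based half-open range,
#'   `0 <= start < end <= n_frames`.
#' @return An `height x width` matrix.
#' @export
build_reference <- function(stack, start_frame, end_frame) {
  nf <- n_frames(stack)
  if (start_frame < 0 || end_frame > nf || start_frame >= end_frame)
    stop(sprintf("build_reference: range [%d, %d) invalid for %d frames",
                 start_frame, end_frame, nf))
  idx <- (start_frame + 1L):end_frame
  d <- frame_dim(stack)
  sub <- stack$data[idx, , , drop = FALSE]
  matrix(colMeans(matrix(sub, length(idx), d[1] * d[2])), d[1], d[2])
}

# --- FFT machinery -----------------------------------------------------

.hann2 <- function(h, w) {
  wy <- 0.5 * (1 - cos(2 * pi * (0:(h - 1)) / (h - 1)))
  wx <- 0.5 * (1 - cos(2 * pi * (0:(w - 1)) / (w - 1)))
  outer(wy, wx)
}

.fftshift2 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  m[c((floor(h / 2) + 1):h, 1:floor(h / 2)),
    c((floor(w / 2) + 1):w, 1:floor(w / 2))]
}

# difference-of-Hanning highpass emphasis on the centred spectrum
.spectral_highpass <- function(h, w) {
  fy <- ((0:(h - 1)) - floor(h / 2)) / h
  fx <- ((0:(w - 1)) - floor(w / 2)) / w
  cp <- outer(cos(pi * fy), cos(pi * fx))
  (1 - cp) * (2 - cp)
}

# cross-power spectrum correlation surface of two same-size matrices
.phase_corr_surface <- function(a, b) {
  fa <- stats::fft(a); fb <- stats::fft(b)
  r <- fb * Conj(fa)
  r <- r / pmax(Mod(r), .Machine$double.eps)
  Re(stats::fft(r, inverse = TRUE)) / length(r)
}

.subpix1 <- function(cm1, c0, cp1) {
  den <- cm1 - 2 * c0 + cp1
  if (!is.finite(den) || abs(den) < 1e-300) return(0)
  max(-0.5, min(0.5, 0.5 * (cm1 - cp1) / den))
}

# subpixel peak (ex, ey) of a correlation surface at 0-based (px, py)
.cc_peak <- function(cc, pk) {
  h <- nrow(cc); w <- ncol(cc)
  py <- (pk - 1) %% h
  px <- (pk - 1) %/% h
  wrap <- function(i, n) (i %% n) + 1            # 0-based -> 1-based circular
  dy <- .subpix1(cc[wrap(py - 1, h), px + 1], cc[py + 1, px + 1],
                 cc[wrap(py + 1, h), px + 1])
  dx <- .subpix1(cc[py + 1, wrap(px - 1, w)], cc[py + 1, px + 1],
                 cc[py + 1, wrap(px + 1, w)])
  ey <- py + dy; ex <- px + dx
  if (ey > h / 2) ey <- ey - h
  if (ex > w / 2) ex <- ex - w
  list(ex = ex, ey = ey, peak = cc[pk])
}

# cross-power phase correlation: returns subpixel (ex, ey) such that
# b(x, y) ~= a(x - ex, y - ey); also the peak height for disambiguation
.phase_correlate <- function(a, b) {
  cc <- .phase_corr_surface(a, b)
  .cc_peak(cc, which.max(cc))
}

# top-k well-separated local maxima of a correlation surface
.cc_top_peaks <- function(cc, k = 3L, exclude = 5L) {
  peaks <- list()
  h <- nrow(cc); w <- ncol(cc)
  tmp <- cc
  for (i in seq_len(k)) {
    pk <- which.max(tmp)
    if (!is.finite(tmp[pk])) break
    peaks[[i]] <- .cc_peak(cc, pk)
    py <- (pk - 1) %% h; px <- (pk - 1) %/% h
    ys <- ((py - exclude):(py + exclude)) %% h + 1
    xs <- ((px - exclude):(px + exclude)) %% w + 1
    tmp[ys, xs] <- -Inf
  }
  peaks
}

# centred log-magnitude spectrum with highpass emphasis
.prep_spectrum <- function(frame) {
  f <- frame
  f[!is.finite(f)] <- mean(f[is.finite(f)])
  f <- (f - mean(f)) * .hann2(nrow(f), ncol(f))
  m <- .fftshift2(Mod(stats::fft(f)))
  log1p(m) * .spectral_highpass(nrow(f), ncol(f))
}

# bilinear sample of matrix m at 0-based fractional (x, y); outside -> 0
.sample_bilinear <- function(m, x, y) {
  h <- nrow(m); w <- ncol(m)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  g <- function(xi, yi) {
    ok <- xi >= 0 & xi < w & yi >= 0 & yi < h
    v <- numeric(length(xi))
    v[ok] <- m[cbind(yi[ok] + 1L, xi[ok] + 1L)]
    v
  }
  (1 - fx) * (1 - fy) * g(x0, y0) + fx * (1 - fy) * g(x0 + 1, y0) +
    (1 - fx) * fy * g(x0, y0 + 1) + fx * fy * g(x0 + 1, y0 + 1)
}

# log-polar resampling of a centred spectrum over a half circle
# rows: log-radius (nr samples, 1 .. rmax), cols: angle (ntheta over pi)
.log_polar <- function(m, nr = 384L, ntheta = 720L) {
  h <- nrow(m); w <- ncol(m)
  cy <- floor(h / 2); cx <- floor(w / 2)
  rmax <- min(h, w) / 2 - 1
  dlog <- log(rmax) / (nr - 1)
  rr <- exp((0:(nr - 1)) * dlog)
  th <- (0:(ntheta - 1)) * pi / ntheta
  xs <- outer(rr, cos(th)) + cx
  ys <- outer(rr, sin(th)) + cy
  lp <- matrix(.sample_bilinear(m, as.vector(xs), as.vector(ys)), nr, ntheta)
  # taper the non-periodic radial axis
  lp <- lp * (0.5 * (1 - cos(2 * pi * (0:(nr - 1)) / (nr - 1))))
  list(lp = lp, dlog = dlog, dtheta = pi / ntheta)
}

#' Estimate the rigid transform aligning one frame to a reference
#'
#' Rotation and scale are recovered first by phase-correlating the
#' log-polar resampled magnitude spectra of the two frames (translation
#' drops out of the magnitude spectrum; rotation and scale become circular
#' and log-radial shifts). The moving frame is then de-rotated/de-scaled
#' and the residual translation recovered by subpixel phase correlation;
#' the 180-degree rotation ambiguity inherent in magnitude spectra is
#' resolved by keeping the candidate with the stronger correlation peak.
#'
#' @param moving,reference same-size numeric matrices with nonzero
#'   variance; `NaN` pixels are replaced by the frame mean for estimation.
#' @return A [rigid_transform()] `t` such that `apply_transform(moving, t)`
#'   best matches `reference`.
#' @export
estimate_transform <- function(moving, reference) {
  if (!all(dim(moving) == dim(reference)))
    stop("estimate_transform: frames differ in size")
  if (stats::sd(moving[is.finite(moving)]) == 0 ||
      stats::sd(reference[is.finite(reference)]) == 0)
    stop("estimate_transform: constant frame")
  sm <- .prep_spectrum(moving)
  sr <- .prep_spectrum(reference)
  lm <- .log_polar(sm)
  lr <- .log_polar(sr, nr = nrow(lm$lp), ntheta = ncol(lm$lp))
  lp_cc <- .phase_corr_surface(lr$lp, lm$lp)
  prep <- function(f) {
    f[!is.finite(f)] <- mean(f[is.finite(f)])
    (f - mean(f)) * .hann2(nrow(f), ncol(f))
  }
  ref_w <- prep(reference)
  best <- NULL
  # weakly textured frames can throw spurious log-polar peaks (e.g. the
  # 90-degree harmonics of a rectangular content boundary), so scan the
  # top peaks plus the 180-degree magnitude ambiguity and keep the
  # candidate with the strongest translation correlation
  for (cand in .cc_top_peaks(lp_cc, k = 3L)) {
    # |F_mov|(k) = s^2 |F_ref|(s R(-theta) k): radius log-shifts by
    # -log(s), angle by +theta, for a motion ref -> moving
    s_mov <- exp(-cand$ey * lm$dlog)
    th_base <- cand$ex * lm$dtheta * 180 / pi
    for (th in c(th_base, th_base + 180)) {
      t_lin_inv <- rigid_transform(0, 0, -th, 1 / s_mov)
      m2 <- apply_transform(moving, t_lin_inv)
      pc2 <- .phase_correlate(ref_w, prep(m2))
      if (is.null(best) || pc2$peak > best$peak)
        best <- list(peak = pc2$peak, th = th, s = s_mov,
                     ex = pc2$ex, ey = pc2$ey)
    }
  }
  # motion: moving = T_d (S_{theta, s} (reference)); de-scaled moving is the
  # reference shifted by e = A^{-1} d, so d = s R(theta) e
  a <- best$th * pi / 180
  dx <- best$s * (cos(a) * best$ex - sin(a) * best$ey)
  dy <- best$s * (sin(a) * best$ex + cos(a) * best$ey)
  invert_transform(rigid_transform(dx, dy, best$th, best$s))
}

#' Align every stack of a project run to a reference frame
#'
#' Estimates one transform from a single frame of the stack (movement
#' within a stack is assumed negligible) and applies it to all frames.
#'
#' @param stack an [image_stack()].
#' @param reference reference frame matrix (see [build_reference()]).
#' @param frame_index 0-based index of the frame used for estimation.
#' @return A list with the aligned `stack` and the estimated `transform`.
#' @export
align_stack <- function(stack, reference, frame_index = 0L) {
  t <- estimate_transform(get_frame(stack, frame_index), reference)
  list(stack = apply_transform(stack, t), transform = t)
}
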