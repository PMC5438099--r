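#' Trim frames from the front and back of a stack
#'
#' Mechanical settling at recording onset contaminates the first frames;
#' deleting e.g. the first 20 frames is a standard precaution.
#'
#' @param stack an [image_stack()].
#' @param n_front,n_back number of frames to drop at each end;
#'   `n_front + n_back < n_frames(stack)`.
#' @return The trimmed [image_stack()].
#' @export
trim_frames <- function(stack, n_front = 0L, n_back = 0L) {
  nf <- n_frames(stack)
  if (n_front < 0 || n_back < 0 || n_front + n_back >= nf)
    stop(sprintf("trim_frames: cannot drop %d + %d of %d frames",
                 n_front, n_back, nf))
  if (n_front == 0 && n_back == 0) return(stack)
  image_stack(stack$data[(n_front + 1L):(nf - n_back), , , drop = FALSE],
              stack$fps)
}

# steady-state initial filter state for a step input of unit height
# (companion-matrix solve, as conventional for forward-backward filtering)
.lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  a <- c(a, numeric(n - length(a)))
  b <- c(b, numeric(n - length(b)))
  b <- b / a[1]; a <- a / a[1]
  comp_t <- cbind(-a[2:n], rbind(diag(1, n - 2), 0))   # companion(a)^T
  solve(diag(1, n - 1) - comp_t, b[2:n] - a[2:n] * b[1])
}

# direct-form-II-transposed IIR filter down the rows of X (time x pixels),
# all columns at once; zi scaled by the first row when given
.iir_filter_mat <- function(b, a, x, zi = NULL) {
  n <- max(length(a), length(b))
  a <- c(a, numeric(n - length(a)))
  b <- c(b, numeric(n - length(b)))
  b <- b / a[1]; a <- a / a[1]
  np <- ncol(x); nt <- nrow(x)
  z <- if (is.null(zi)) matrix(0, n - 1, np) else outer(zi, x[1, ])
  y <- x
  for (t in seq_len(nt)) {
    xt <- x[t, ]
    yt <- b[1] * xt + z[1, ]
    if (n > 2)
      for (k in seq_len(n - 2))
        z[k, ] <- b[k + 1] * xt + z[k + 1, ] - a[k + 1] * yt
    z[n - 1, ] <- b[n] * xt - a[n] * yt
    y[t, ] <- yt
  }
  y
}

# zero-phase forward-backward filtering with odd-reflection padding,
# vectorised over pixels
.filtfilt_mat <- function(b, a, x) {
  padlen <- 3L * max(length(a), length(b))
  nt <- nrow(x)
  if (nt <= padlen)
    stop("zero-phase filtering needs more than ", padlen, " frames, got ", nt)
  pre <- 2 * x[rep(1L, padlen), , drop = FALSE] -
    x[(padlen + 1L):2L, , drop = FALSE]
  post <- 2 * x[rep(nt, padlen), , drop = FALSE] -
    x[(nt - 1L):(nt - padlen), , drop = FALSE]
  xp <- rbind(pre, x, post)
  zi <- .lfilter_zi(b, a)
  y <- .iir_filter_mat(b, a, xp, zi)
  y <- y[nrow(y):1L, , drop = FALSE]
  y <- .iir_filter_mat(b, a, y, zi)
  y <- y[nrow(y):1L, , drop = FALSE]
  y[(padlen + 1L):(padlen + nt), , drop = FALSE]
}

.cheby_design <- function(low_hz, high_hz, order, ripple_db, fps) {
  nyq <- fps / 2
  if (!(0 < low_hz && low_hz < high_hz && high_hz < nyq))
    stop(sprintf("bandpass edges must satisfy 0 < %g < %g < Nyquist (%g Hz)",
                 low_hz, high_hz, nyq))
  if (order < 1) stop("filter order must be >= 1")
  if (ripple_db <= 0) stop("passband ripple must be > 0 dB")
  fl <- signal::cheby1(order, ripple_db, c(low_hz, high_hz) / nyq,
                       type = "pass")
  list(b = fl$b, a = fl$a)
}

#' Zero-phase Chebyshev type-I bandpass
#'
#' Each pixel's time series is filtered with a type-I Chebyshev bandpass
#' (the reference configuration is order 4, 0.1 dB passband ripple,
#' 0.3-3.0 Hz at 30 fps), applied forward and backward so the result has
#' zero phase lag -- a prerequisite for zero-lag correlation downstream.
#' Padding is by odd reflection at both ends. DC and the cardiac band are
#' rejected; undefined pixels stay undefined.
#'
#' With `keep_baseline = TRUE` each pixel's pre-filter temporal mean is
#' added back after filtering. The bandpass itself has zero gain at DC, so
#' a subsequent dF/F0 step (which divides by the temporal mean) would be
#' ill-posed on plain bandpassed data; the pipeline's `bandpass` step
#' therefore re-adds the baseline by default, keeping the reference order
#' bandpass -> dF/F0 well-defined.
#'
#' @param stack an [image_stack()].
#' @param low_hz,high_hz passband edges in Hz, `0 < low < high < fps/2`.
#' @param order filter order (>= 1).
#' @param ripple_db maximum passband ripple in dB.
#' @param keep_baseline add each pixel's pre-filter temporal mean back to
#'   the filtered series (default `FALSE`: a pure bandpass).
#' @return The filtered [image_stack()].
#' @export
cheby_bandpass <- function(stack, low_hz = 0.3, high_hz = 3.0, order = 4L,
                           ripple_db = 0.1, keep_baseline = FALSE) {
  fl <- .cheby_design(low_hz, high_hz, order, ripple_db, stack$fps)
  x <- .stack_to_mat(stack)
  m <- .filtfilt_mat(fl$b, fl$a, x)
  if (keep_baseline) m <- sweep(m, 2L, colMeans(x), "+")
  .mat_to_stack(m, frame_dim(stack), stack$fps)
}

#' Single-pass gain of the designed bandpass at given frequencies
#'
#' Evaluates `|H(f)|` of the Chebyshev design on the unit circle; the
#' zero-phase (forward-backward) application of [cheby_bandpass()] has gain
#' `|H(f)|^2`.
#'
#' @inheritParams cheby_bandpass
#' @param freq_hz frequencies to evaluate, in Hz.
#' @param fps sampling rate in Hz.
#' @param zero_phase if `TRUE` (default) return the forward-backward gain
#'   `|H|^2`, else the single-pass `|H|`.
#' @return Numeric vector of gains.
#' @export
cheby_gain <- function(freq_hz, low_hz = 0.3, high_hz = 3.0, order = 4L,
                       ripple_db = 0.1, fps = 30, zero_phase = TRUE) {
  fl <- .cheby_design(low_hz, high_hz, order, ripple_db, fps)
  w <- 2 * pi * freq_hz / fps
  ev <- function(coef, w) {
    k <- seq_along(coef) - 1
    vapply(w, function(wi) sum(coef * exp(-1i * wi * k)), complex(1))
  }
  g <- Mod(ev(fl$b, w) / ev(fl$a, w))
  if (zero_phase) g^2 else g
}

#' Fractional fluorescence change (dF/F0)
#'
#' Per pixel, the baseline `F0` is the mean over all frames and the output
#' is `(F - F0) / F0`, making the signal robust to uneven illumination and
#' slow baseline drift. Pixels with `F0 = 0` cannot be normalised and
#' become undefined (a message reports how many).
#'
#' @param stack an [image_stack()].
#' @return The normalised [image_stack()]; every defined pixel has exactly
#'   zero temporal mean.
#' @export
dff <- function(stack) {
  m <- .stack_to_mat(stack)
  f0 <- colMeans(m)
  zero <- which(is.finite(f0) & f0 == 0)
  if (length(zero) > 0) {
    message("dff: ", length(zero), " pixel(s) with zero baseline set to undefined")
    f0[zero] <- NaN
  }
  m <- sweep(m, 2L, f0, "/") - 1
  .mat_to_stack(m, frame_dim(stack), stack$fps)
}

#' Global signal of a stack
#'
#' Per-frame mean over all defined pixels -- the brain-wide component that
#' global signal regression removes.
#'
#' @param stack an [image_stack()].
#' @return Numeric vector of length `n_frames(stack)`.
#' @export
global_signal <- function(stack) {
  m <- .stack_to_mat(stack)
  if (all(!is.finite(m[1L, ])))
    stop("global_signal: stack has no defined pixels")
  rowMeans(m, na.rm = TRUE)
}

#' Global signal regression (GSR)
#'
#' Removes, pixel by pixel, the frame-wise spatial mean signal by ordinary
#' least squares on (intercept, global signal); the output is the residual
#' series. The global signal is computed over defined pixels only, so
#' masked borders do not contaminate it. Residuals are exactly orthogonal
#' to the global signal at every pixel and average spatially to the zero
#' series; undefined pixels propagate.
#'
#' @param stack an [image_stack()] with at least 3 frames.
#' @return The residual [image_stack()].
#' @export
gsr <- function(stack) {
  if (n_frames(stack) < 3L) stop("gsr: at least 3 frames required")
  g <- global_signal(stack)
  if (stats::sd(g) == 0) stop("gsr: global signal is constant")
  x <- cbind(1, g)
  m <- .stack_to_mat(stack)
  beta <- solve(crossprod(x), crossprod(x, m))
  .mat_to_stack(m - x %*% beta, frame_dim(stack), stack$fps)
}

#' Concatenate stacks along time
#'
#' Trials are appended in list order so correlation can use the full
#' recorded history as one continuous series.
#'
#' @param stacks list of [image_stack()]s with identical frame size and fps.
#' @return One [image_stack()] with `sum(n_frames)` frames.
#' @export
concat_stacks <- function(stacks) {
  if (length(stacks) == 0L) stop("concat_stacks: empty list")
  if (length(stacks) == 1L) return(stacks[[1L]])
  hw <- frame_dim(stacks[[1L]]); fps <- stacks[[1L]]$fps
  for (s in stacks[-1L]) {
    if (!all(frame_dim(s) == hw)) stop("concat_stacks: frame size mismatch")
    if (s$fps != fps) stop("concat_stacks: fps mismatch")
  }
  nfs <- vapply(stacks, n_frames, integer(1))
  out <- array(0, dim = c(sum(nfs), hw))
  at <- 0L
  for (s in stacks) {
    out[(at + 1L):(at + n_frames(s)), , ] <- s$data
    at <- at + n_frames(s)
  }
  image_stack(out, fps)
}

#' Elementwise stack division
#'
#' Dividing a fluorescence dF/F0 stack by the matching intrinsic
#' reflectance dF/F0 stack is a simple hemodynamic correction. Sites where
#' the denominator is zero become undefined.
#'
#' @param numerator,denominator same-shape [image_stack()]s.
#' @return The ratio [image_stack()].
#' @export
divide_stacks <- function(numerator, denominator) {
  if (!all(dim(numerator$data) == dim(denominator$data)))
    stop("divide_stacks: shape mismatch")
  out <- numerator$data / denominator$data
  out[denominator$data == 0] <- NaN
  image_stack(out, numerator$fps)
}

#' Evoked (trial) average
#'
#' Frame-by-frame mean across trials; residual noise shrinks as
#' `1/sqrt(n_trials)` around the deterministic evoked response.
#'
#' @param stacks list of same-shape [image_stack()]s (trials).
#' @param truncate_to_shortest if `TRUE`, unequal-length trials are cut to
#'   the shortest; otherwise unequal lengths are an error.
#' @return The averaged [image_stack()].
#' @export
evoked_average <- function(stacks, truncate_to_shortest = FALSE) {
  if (length(stacks) == 0L) stop("evoked_average: empty list")
  hw <- frame_dim(stacks[[1L]])
  if (!all(vapply(stacks, function(s) all(frame_dim(s) == hw), logical(1))))
    stop("evoked_average: frame size mismatch")
  nfs <- vapply(stacks, n_frames, integer(1))
  if (length(unique(nfs)) > 1L) {
    if (!truncate_to_shortest)
      stop("evoked_average: trial lengths differ (",
           paste(nfs, collapse = ", "),
           "); set truncate_to_shortest = TRUE to cut to the shortest")
    stacks <- lapply(stacks, function(s)
      trim_frames(s, 0L, n_frames(s) - min(nfs)))
  }
  acc <- stacks[[1L]]$data
  for (s in stacks[-1L]) acc <- acc + s$data
  image_stack(acc / length(stacks), stacks[[1L]]$fps)
}

#' Temporal standard-deviation map
#'
#' Per-pixel standard deviation over frames (population convention,
#' divisor `n`); active regions light up, quiet ones stay dark.
#'
#' @param stack an [image_stack()] with at least 2 frames.
#' @return A `height x width` matrix.
#' @export
stdev_map <- function(stack) {
  if (n_frames(stack) < 2L) stop("stdev_map: at least 2 frames required")
  m <- .stack_to_mat(stack)
  mu <- colMeans(m)
  v <- colMeans(sweep(m, 2L, mu)^2)
  matrix(sqrt(v), frame_dim(stack)[1L], frame_dim(stack)[2L])
}
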