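#' Synthetic widefield stack configuration
#'
#' Ground-truth generator emulating the study conditions of a widefield
#' GCaMP recording: 256 x 256 pixels at 30 Hz, disk-shaped cortical regions
#' driven by band-limited Gaussian sources with a controllable zero-lag
#' correlation structure, a shared slow global confound, a cardiac-band
#' sinusoid, per-pixel white noise, and an optional planted rigid motion.
#'
#' Source series are smoothed white noise, empirically whitened and then
#' re-coloured with the symmetric square root of `source_correlations`, so the
#' realised zero-lag sample correlation matrix of the sources equals the
#' target exactly; Monte-Carlo sampling error then cannot masquerade as an
#' analysis error when recovery is tested.
#'
#' @param height,width frame size in pixels.
#' @param n_frames frames per stack (900 = 30 s at 30 Hz).
#' @param fps frame rate in Hz.
#' @param regions list of regions, each
#'   `list(center = c(x_px, y_px), radius = px, source = k)`; overlapping
#'   regions sum their sources.
#' @param source_correlations symmetric positive-semidefinite matrix of
#'   target pairwise zero-lag correlations among sources (unit diagonal).
#' @param source_amp amplitude of the regional sources as a fraction of
#'   baseline (0.05 = 5 percent dF/F, typical of strong GCaMP6 activity).
#' @param global_amplitude amplitude of the shared global confound
#'   (fraction of baseline; same scale as `source_amp`).
#' @param heartbeat_hz frequency of the cardiac confound (8 Hz sits in the
#'   murine cardiac band and above the 3 Hz passband edge).
#' @param heartbeat_amp amplitude of the cardiac sinusoid.
#' @param noise_sigma per-pixel white-noise level (fraction of baseline).
#' @param baseline mean intensity (arbitrary camera units, > 0).
#' @param smooth_len moving-average window (frames) band-limiting the
#'   sources; 8 frames at 30 fps keeps most power below ~3 Hz.
#' @param rigid_motion optional [rigid_transform()] applied to the whole
#'   stack after synthesis.
#' @param seed RNG seed; the same configuration and seed give bit-identical
#'   stacks.
#' @return A `synth_config` list.
#' @export
synth_config <- function(height = 256L, width = 256L, n_frames = 900L,
                         fps = 30, regions = NULL,
                         source_correlations = NULL, source_amp = 0.05,
                         global_amplitude = 0.05, heartbeat_hz = 8,
                         heartbeat_amp = 0.02, noise_sigma = 0.01,
                         baseline = 100, smooth_len = 8L,
                         rigid_motion = NULL, seed = 1L) {
  if (is.null(regions))
    regions <- list(
      list(center = c(width * 0.25, height * 0.5), radius = min(height, width) / 8,
           source = 1L),
      list(center = c(width * 0.75, height * 0.5), radius = min(height, width) / 8,
           source = 2L))
  n_src <- max(vapply(regions, function(r) as.integer(r$source), integer(1)))
  if (is.null(source_correlations)) source_correlations <- diag(1, n_src)
  if (!isSymmetric(unname(source_correlations)) ||
      any(abs(diag(source_correlations) - 1) > 1e-12))
    stop("synth_config: source_correlations must be symmetric with unit diagonal")
  if (noise_sigma < 0) stop("synth_config: noise_sigma must be >= 0")
  if (baseline <= 0) stop("synth_config: baseline must be > 0")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_frames = as.integer(n_frames), fps = fps,
                 regions = regions,
                 source_correlations = source_correlations,
                 source_amp = source_amp,
                 global_amplitude = global_amplitude,
                 heartbeat_hz = heartbeat_hz, heartbeat_amp = heartbeat_amp,
                 noise_sigma = noise_sigma, baseline = baseline,
                 smooth_len = as.integer(smooth_len),
                 rigid_motion = rigid_motion, seed = as.integer(seed)),
            class = "synth_config")
}

# circularly smoothed unit-variance Gaussian series, one per column
.smooth_noise <- function(n_frames, n_series, smooth_len) {
  w <- matrix(stats::rnorm(n_frames * n_series), n_frames, n_series)
  if (smooth_len > 1L) {
    k <- rep(1 / smooth_len, smooth_len)
    w <- apply(w, 2L, function(col)
      as.numeric(stats::filter(col, k, sides = 2L, circular = TRUE)))
    w <- matrix(w, n_frames, n_series)
  }
  w
}

# band-limited sources with EXACT zero-lag sample correlation = target
.synth_sources <- function(cfg) {
  set.seed(cfg$seed)
  n_src <- nrow(cfg$source_correlations)
  s <- .smooth_noise(cfg$n_frames, n_src, cfg$smooth_len)
  s <- sweep(s, 2L, colMeans(s))
  emp <- crossprod(s) / (cfg$n_frames - 1)
  s <- s %*% backsolve(chol(emp), diag(n_src))     # exact whitening
  # symmetric PSD square root so exactly singular targets (rho = 1) work
  eg <- eigen(cfg$source_correlations, symmetric = TRUE)
  if (min(eg$values) < -1e-8)
    stop("synth_config: source_correlations is not positive semidefinite")
  rt <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  src <- s %*% rt
  # global confound: smoothed noise made exactly orthogonal to the sources
  g <- .smooth_noise(cfg$n_frames, 1L, cfg$smooth_len * 2L)
  g <- g - mean(g)
  g <- qr.resid(qr(src), g)            # rank-safe (sources may coincide)
  g <- as.numeric(g) / stats::sd(g)
  list(sources = src, global = g)
}

#' Generate one ground-truth synthetic stack
#'
#' See [synth_config()] for the model. Each pixel is
#' `baseline * (1 + region source + global_amplitude * global +
#' heartbeat sinusoid + noise)`, where the region source is the pixel's
#' (summed, for overlaps) unit-variance source scaled by `source_amp`.
#'
#' @param cfg a [synth_config()].
#' @param sources optional precomputed `list(sources, global)` from a
#'   previous call, so several stacks can share sources while drawing
#'   independent noise (trials of the same animal).
#' @return `list(stack = image_stack, truth = list(...))`; `truth` records
#'   the source series, global series, per-region pixel masks, membership
#'   counts, and the planted motion.
#' @export
generate_stack <- function(cfg, sources = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  if (is.null(sources)) sources <- .synth_sources(cfg)
  set.seed(cfg$seed + 1000003L)       # noise stream, distinct from sources
  tn <- cfg$n_frames; h <- cfg$height; w <- cfg$width
  npix <- h * w
  # membership: pixel x source weight (overlaps sum)
  n_src <- ncol(sources$sources)
  px <- rep(0:(w - 1), each = h); py <- rep(0:(h - 1), times = w)
  memb <- matrix(0, npix, n_src)
  masks <- vector("list", length(cfg$regions))
  for (i in seq_along(cfg$regions)) {
    r <- cfg$regions[[i]]
    inr <- (px - r$center[1])^2 + (py - r$center[2])^2 <= r$radius^2
    memb[inr, r$source] <- memb[inr, r$source] + 1
    masks[[i]] <- matrix(inr, h, w)
  }
  phase <- stats::runif(1, 0, 2 * pi)
  hb <- cfg$heartbeat_amp *
    sin(2 * pi * cfg$heartbeat_hz * (0:(tn - 1)) / cfg$fps + phase)
  m <- (cfg$source_amp * sources$sources) %*% t(memb)     # t x pixel
  m <- m + cfg$global_amplitude * sources$global + hb
  if (cfg$noise_sigma > 0)
    m <- m + cfg$noise_sigma * matrix(stats::rnorm(tn * npix), tn, npix)
  m <- cfg$baseline * (1 + m)
  stack <- .mat_to_stack(m, c(h, w), cfg$fps)
  if (!is.null(cfg$rigid_motion))
    stack <- apply_transform(stack, cfg$rigid_motion)
  list(stack = stack,
       truth = list(sources = sources$sources, global = sources$global,
                    region_masks = masks, membership = memb,
                    motion = cfg$rigid_motion, config = cfg))
}

#' Write a synthetic multi-trial project fixture to disk
#'
#' Lays `n_stacks` single-channel float64 RAW files plus a project manifest
#' in `dir`, emulating a session of repeated 30 s trials: all trials share
#' the same underlying sources but draw independent noise, and each may
#' carry its own planted rigid misalignment. Ground truth is saved as JSON
#' beside the stacks.
#'
#' @param cfg a [synth_config()].
#' @param n_stacks number of trials.
#' @param dir project directory (created if needed).
#' @param motions optional list of [rigid_transform()]s, one per stack.
#' @param um_per_px,origin coordinate-system values stored in the manifest.
#' @return The project (see [create_project()]) with all trials imported.
#' @export
generate_project_fixture <- function(cfg, n_stacks, dir, motions = NULL,
                                     um_per_px = 41, origin = NULL) {
  proj <- create_project(dir)
  proj <- set_project_scale(proj, um_per_px)
  if (!is.null(origin)) proj <- set_project_origin(proj, origin)
  shared <- .synth_sources(cfg)
  spec <- raw_spec(cfg$width, cfg$height, n_channels = 1L,
                   dtype = "float64", channel_index = 0L)
  truth_all <- list()
  for (i in seq_len(n_stacks)) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i
    cfg_i$rigid_motion <- if (!is.null(motions)) motions[[i]] else NULL
    gs <- generate_stack(cfg_i, sources = shared)
    raw_path <- file.path(dir, sprintf("trial_%02d.raw", i))
    write_raw_stack(gs$stack, raw_path, dtype = "float64")
    proj <- import_raw(proj, raw_path, spec, cfg$fps)
    truth_all[[sprintf("trial_%02d", i)]] <- list(
      seed = cfg_i$seed,
      motion = if (is.null(cfg_i$rigid_motion)) NULL else
        unclass(cfg_i$rigid_motion))
  }
  truth <- list(
    n_stacks = n_stacks,
    n_frames = cfg$n_frames, fps = cfg$fps,
    source_correlations = cfg$source_correlations,
    regions = cfg$regions, source_amp = cfg$source_amp,
    global_amplitude = cfg$global_amplitude,
    heartbeat_hz = cfg$heartbeat_hz, noise_sigma = cfg$noise_sigma,
    stacks = truth_all)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       matrix = "rowmajor")
  proj
}

#' Synthetic vessel-like frame for registration tests
#'
#' Dark, gently curving filaments (blood vessels) over a smooth bright
#' fluorescence background -- the image content that log-polar FFT
#' registration keys on.
#'
#' @param height,width frame size in pixels.
#' @param n_vessels number of filaments.
#' @param seed RNG seed.
#' @return A `height x width` matrix.
#' @export
synth_vessel_frame <- function(height = 256L, width = 256L, n_vessels = 12L,
                               seed = 1L) {
  set.seed(seed)
  # smooth background: a few broad Gaussian illumination blobs
  px <- rep(0:(width - 1), each = height); py <- rep(0:(height - 1), times = width)
  bg <- rep(100, height * width)
  for (i in 1:4) {
    cx <- stats::runif(1, 0.2, 0.8) * width
    cy <- stats::runif(1, 0.2, 0.8) * height
    s2 <- (0.35 * min(height, width))^2
    bg <- bg + 40 * exp(-((px - cx)^2 + (py - cy)^2) / (2 * s2))
  }
  img <- matrix(bg, height, width)
  # vessels: curvature-perturbed random walks stamped as dark points
  nsteps <- round(1.2 * min(height, width))
  for (v in seq_len(n_vessels)) {
    x <- stats::runif(1, 0.15, 0.85) * width
    y <- stats::runif(1, 0.15, 0.85) * height
    ang <- stats::runif(1, 0, 2 * pi)
    depth <- stats::runif(1, 25, 60)
    for (s in seq_len(nsteps)) {
      ang <- ang + stats::rnorm(1, 0, 0.08)
      x <- x + cos(ang); y <- y + sin(ang)
      xi <- round(x); yi <- round(y)
      if (xi < 1 || xi > width - 2 || yi < 1 || yi > height - 2) break
      img[yi + 1L, xi + 1L] <- img[yi + 1L, xi + 1L] - depth
    }
  }
  .gaussian_blur(img, 3)
}
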