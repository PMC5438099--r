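# shared fixture builders; everything is generated in code at test time

# stack whose [t, r, c] value is fully determined: t*10000 + r*100 + c
indexed_stack <- function(nf = 4L, h = 3L, w = 5L, fps = 30) {
  a <- array(0, dim = c(nf, h, w))
  for (t in 1:nf) for (r in 1:h) for (cc in 1:w)
    a[t, r, cc] <- t * 10000 + r * 100 + cc
  image_stack(a, fps)
}

# stack built from an explicit time x pixel matrix (pixels fill column-major)
stack_from_mat <- function(m, h, w, fps = 30) {
  image_stack(array(as.vector(m), dim = c(nrow(m), h, w)), fps)
}

rand_stack <- function(nf = 50L, h = 4L, w = 6L, fps = 30, seed = 1L) {
  set.seed(seed)
  image_stack(array(rnorm(nf * h * w, mean = 100, sd = 5),
                    dim = c(nf, h, w)), fps)
}

# the 14 published seed coordinates (microns from bregma, 1-px squares)
table1_df <- function() {
  data.frame(
    name = c("L-V1", "L-BC", "L-HL", "L-M1", "L-M2", "L-RS", "L-AC",
             "R-V1", "R-BC", "R-HL", "R-M1", "R-M2", "R-RS", "R-AC"),
    length = 1,
    x = c(-2516.8, -4300, -1694.2, -1500, -870.02, -620.43, -260,
          2516.8, 4300, 1694.2, 1500, 870.02, 620.43, 260),
    y = c(-4267.8, -760, -1145.7, 2000, 1420.5, -2885.8, 270,
          -4267.8, -760, -1145.7, 2000, 1420.5, -2885.8, 270),
    stringsAsFactors = FALSE)
}

write_table1_csv <- function(path = tempfile(fileext = ".csv")) {
  utils::write.csv(table1_df(), path, row.names = FALSE, quote = FALSE)
  path
}

# smooth test frame (Gaussian blobs) for interpolation round-trips
smooth_frame <- function(h = 64L, w = 64L, seed = 2L) {
  set.seed(seed)
  px <- rep(0:(w - 1), each = h); py <- rep(0:(h - 1), times = w)
  f <- rep(0, h * w)
  for (i in 1:5) {
    cx <- runif(1, 0.2, 0.8) * w; cy <- runif(1, 0.2, 0.8) * h
    s2 <- runif(1, 4, 12)^2
    f <- f + runif(1, 20, 60) * exp(-((px - cx)^2 + (py - cy)^2) / (2 * s2))
  }
  matrix(f + 10, h, w)
}

# two-region config with exactly controllable source correlation
two_region_cfg <- function(rho, n_frames = 2000L, hw = 32L, seed = 11L,
                           noise_sigma = 0, global_amplitude = 0,
                           heartbeat_amp = 0) {
  synth_config(
    height = hw, width = hw, n_frames = n_frames, fps = 30,
    regions = list(
      list(center = c(hw * 0.25, hw * 0.5), radius = hw / 6, source = 1L),
      list(center = c(hw * 0.75, hw * 0.5), radius = hw / 6, source = 2L)),
    source_correlations = matrix(c(1, rho, rho, 1), 2),
    noise_sigma = noise_sigma, global_amplitude = global_amplitude,
    heartbeat_amp = heartbeat_amp, seed = seed)
}

region_center_px <- function(cfg, i) {
  ctr <- cfg$regions[[i]]$center
  c(round(ctr[1]), round(ctr[2]))
}
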