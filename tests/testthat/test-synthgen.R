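test_that("generation is bit-identical for a fixed seed", {
  cfg <- two_region_cfg(rho = 0.3, n_frames = 200, hw = 16, seed = 60,
                        noise_sigma = 0.01, global_amplitude = 0.05,
                        heartbeat_amp = 0.02)
  a <- generate_stack(cfg)
  b <- generate_stack(cfg)
  expect_identical(a$stack$data, b$stack$data)
  cfg2 <- cfg; cfg2$seed <- 61L
  expect_false(identical(generate_stack(cfg2)$stack$data, a$stack$data))
})

test_that("realised source correlations equal the target exactly", {
  rho <- matrix(c(1, 0.5, -0.2, 0.5, 1, 0.1, -0.2, 0.1, 1), 3)
  cfg <- synth_config(height = 16, width = 16, n_frames = 1000,
                      regions = list(
                        list(center = c(4, 8), radius = 2, source = 1L),
                        list(center = c(8, 8), radius = 2, source = 2L),
                        list(center = c(12, 8), radius = 2, source = 3L)),
                      source_correlations = rho, seed = 62)
  gs <- generate_stack(cfg)
  expect_equal(cor(gs$truth$sources), rho, tolerance = 1e-10)
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(synth_config(height = 8, width = 8, n_frames = 50,
                            regions = list(
                              list(center = c(2, 4), radius = 1, source = 1L),
                              list(center = c(6, 4), radius = 1, source = 2L)),
                            source_correlations = bad, seed = 1) |>
                 generate_stack(), "positive semidefinite")
})

test_that("identical sources give r = 1, independent give small r", {
  cfg1 <- two_region_cfg(rho = 1, n_frames = 400, hw = 16, seed = 63)
  gs1 <- generate_stack(cfg1)
  d1 <- dff(gs1$stack)
  m1 <- spc_map(d1, region_center_px(cfg1, 1))
  other <- region_center_px(cfg1, 2)
  expect_equal(m1$values[other[2] + 1, other[1] + 1], 1.0)

  cfg0 <- two_region_cfg(rho = 0, n_frames = 400, hw = 16, seed = 64)
  gs0 <- generate_stack(cfg0)
  m0 <- spc_map(dff(gs0$stack), region_center_px(cfg0, 1))
  expect_lt(abs(m0$values[other[2] + 1, other[1] + 1]), 0.1)
})

test_that("the cardiac-band confound is removed by the reference bandpass", {
  cfg <- synth_config(height = 4, width = 4, n_frames = 600, fps = 30,
                      regions = list(list(center = c(2, 2), radius = 1,
                                          source = 1L)),
                      source_amp = 0, global_amplitude = 0,
                      heartbeat_hz = 8, heartbeat_amp = 0.02,
                      noise_sigma = 0, seed = 65)
  gs <- generate_stack(cfg)
  # quadrature amplitude of the 8 Hz component before and after filtering
  amp_at <- function(v, f, fps) {
    t <- (seq_along(v) - 1) / fps
    v <- v - mean(v)
    2 * Mod(mean(v * exp(-2i * pi * f * t)))
  }
  before <- amp_at(gs$stack$data[, 4, 4], 8, 30)
  filt <- cheby_bandpass(gs$stack)
  after <- amp_at(filt$data[, 4, 4], 8, 30)
  expect_gt(before, 1)                             # confound is present
  expect_lt(after / before, 0.05)
})

test_that("project fixtures land on disk with manifest and ground truth", {
  cfg <- two_region_cfg(rho = 0.5, n_frames = 90, hw = 12, seed = 66,
                        noise_sigma = 0.005)
  dir <- tempfile("fix")
  proj <- generate_project_fixture(cfg, 4, dir)
  expect_length(project_files(proj), 4)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  expect_length(list.files(dir, pattern = "\\.raw$"), 4)
  # trials share sources: region time courses correlate strongly across
  # trials even with independent noise
  s1 <- project_stack(proj, "trial_01")
  s2 <- project_stack(proj, "trial_02")
  ctr <- region_center_px(cfg, 1)
  r12 <- cor(s1$data[, ctr[2] + 1, ctr[1] + 1],
             s2$data[, ctr[2] + 1, ctr[1] + 1])
  expect_gt(r12, 0.9)
  # concatenation of all trials has the full frame count
  all4 <- concat_stacks(lapply(project_files(proj),
                               function(nm) project_stack(proj, nm)))
  expect_equal(n_frames(all4), 4 * 90L)
})

test_that("single-trial correlation matrices have zero dispersion", {
  cfg <- two_region_cfg(rho = 0.5, n_frames = 120, hw = 12, seed = 67)
  dir <- tempfile("fix1")
  proj <- generate_project_fixture(cfg, 1, dir)
  proj <- set_project_origin(proj, c(6, 6))
  rois <- data.frame(name = c("A", "B"), length = 1,
                     x = 41 * (c(3, 9) - 6), y = 0)
  cm <- correlation_matrix(list(project_stack(proj, "trial_01")), rois,
                           project_cs(proj))
  expect_true(all(cm$std_r == 0))
  expect_equal(cm$n_stacks, 1L)
})

test_that("planted per-trial misalignments are recovered by align", {
  cfg <- synth_config(height = 96, width = 96, n_frames = 40, fps = 30,
                      regions = list(list(center = c(48, 48), radius = 10,
                                          source = 1L)),
                      noise_sigma = 0.002, seed = 68)
  motions <- list(rigid_transform(0, 0, 0, 1),
                  rigid_transform(4, -3, 5, 1.02))
  # overlay a vessel pattern so registration has structure to key on
  vess <- synth_vessel_frame(96, 96, seed = 70)
  mk <- function(i) {
    gs <- generate_stack(cfg)
    st <- gs$stack
    for (t in seq_len(n_frames(st)))
      st$data[t, , ] <- st$data[t, , ] + vess
    apply_transform(st, motions[[i]])
  }
  ref_stack <- mk(1)
  ref <- build_reference(unsharp_filter(ref_stack, 8), 0, 40)
  res <- align_stack(mk(2), ref)
  ti <- invert_transform(motions[[2]])
  expect_lt(sqrt((res$transform$dx - ti$dx)^2 +
                   (res$transform$dy - ti$dy)^2), 0.5)
  expect_lt(abs(res$transform$theta - ti$theta), 1)
  expect_lt(abs(res$transform$scale - ti$scale), 0.02)
})
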