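test_that("frame trimming drops the requested counts and validates them", {
  s <- indexed_stack(nf = 100, h = 2, w = 2)
  tr <- trim_frames(s, 20, 0)
  expect_equal(n_frames(tr), 80L)
  expect_equal(get_frame(tr, 0), get_frame(s, 20))
  expect_identical(trim_frames(s, 0, 0), s)
  expect_error(trim_frames(s, 60, 60), "cannot drop")
})

test_that("bandpass rejects DC, passes 1 Hz, stops 10 Hz at 30 fps", {
  n <- 900; fps <- 30; t <- (0:(n - 1)) / fps
  as_stack <- function(v) image_stack(array(v, dim = c(n, 1, 1)), fps)
  dc <- cheby_bandpass(as_stack(rep(5, n)))
  expect_lt(max(abs(dc$data)) / 5, 1e-6)
  # steady-state amplitude vs the designed filter's frequency response
  mid <- 300:600
  amp1 <- max(abs(cheby_bandpass(as_stack(sin(2 * pi * 1 * t)))$data[mid, , ]))
  expect_gte(amp1, 0.95)
  expect_equal(amp1, cheby_gain(1), tolerance = 0.01)
  amp10 <- max(abs(cheby_bandpass(as_stack(sin(2 * pi * 10 * t)))$data[mid, , ]))
  expect_lte(amp10, 0.05)
  # keep_baseline restores the pre-filter temporal mean (so a following
  # dF/F0 divides by the true baseline instead of filter round-off)
  sig <- as_stack(100 + sin(2 * pi * 1 * t))
  kb <- cheby_bandpass(sig, keep_baseline = TRUE)
  pure <- cheby_bandpass(sig)
  expect_equal(kb$data, pure$data + mean(sig$data))
  expect_error(cheby_bandpass(as_stack(rep(1, n)), low_hz = 0.3,
                              high_hz = 20), "Nyquist")
  expect_error(cheby_bandpass(image_stack(array(1, c(10, 1, 1)), fps)),
               "more than")
})

test_that("bandpass is linear and zero-phase, and keeps NaN pixels NaN", {
  set.seed(9)
  n <- 600; fps <- 30
  x <- rnorm(n); y <- rnorm(n)
  f <- function(v) as.vector(cheby_bandpass(
    image_stack(array(v, c(n, 1, 1)), fps))$data)
  expect_equal(f(2 * x + 3 * y), 2 * f(x) + 3 * f(y), tolerance = 1e-9)
  # in-band sinusoid comes out with zero lag
  s <- sin(2 * pi * 1 * (0:(n - 1)) / fps)
  cc <- stats::ccf(f(s)[100:500], s[100:500], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # undefined pixel stays undefined
  st <- rand_stack(nf = n, h = 2, w = 2)
  st$data[, 1, 1] <- NaN
  out <- cheby_bandpass(st)
  expect_true(all(is.nan(out$data[, 1, 1])))
  expect_true(all(is.finite(out$data[, 2, 2])))
})

test_that("dff normalises to the all-frame mean baseline", {
  s <- stack_from_mat(cbind(c(8, 12), c(5, 5), c(0, 0)), 1, 3)
  out <- suppressMessages(dff(s))
  expect_equal(out$data[, 1, 1], c(-0.2, 0.2))
  expect_equal(out$data[, 1, 2], c(0, 0))
  expect_true(all(is.nan(out$data[, 1, 3])))      # zero baseline
  expect_message(dff(s), "zero baseline")
})

test_that("dff output has zero temporal mean at every defined pixel", {
  s <- rand_stack(nf = 200, h = 5, w = 5, seed = 3)
  out <- dff(s)
  m <- colMeans(matrix(out$data, 200))
  expect_lt(max(abs(m)), 1e-12)
})

test_that("global signal averages defined pixels per frame", {
  s <- stack_from_mat(cbind(c(0, 2), c(2, 0)), 1, 2)
  expect_equal(global_signal(s), c(1, 1))
  shared <- rand_stack(nf = 30, h = 1, w = 1, seed = 5)
  rep4 <- stack_from_mat(matrix(rep(shared$data, 4), 30), 2, 2)
  expect_equal(global_signal(rep4), as.vector(shared$data))
  s2 <- rand_stack(nf = 20, h = 3, w = 3, seed = 6)
  s2$data[, 2, 2] <- NaN                           # masked pixel is excluded
  manual <- sapply(1:20, function(t) mean(s2$data[t, , ], na.rm = TRUE))
  expect_equal(global_signal(s2), manual)
  all_nan <- image_stack(array(NaN, c(5, 2, 2)), 30)
  expect_error(global_signal(all_nan), "no defined pixels")
})

test_that("gsr removes exactly the global component", {
  set.seed(8)
  g <- rnorm(100)
  alpha <- runif(9, -2, 2); beta <- runif(9, 0.5, 2)
  m <- sapply(1:9, function(j) alpha[j] + beta[j] * g)
  out <- gsr(stack_from_mat(m, 3, 3))
  expect_lt(max(abs(out$data)), 1e-10)             # perfect fit -> zero
})

test_that("gsr residuals are orthogonal to g with zero spatial mean", {
  s <- rand_stack(nf = 150, h = 6, w = 6, seed = 12)
  g <- global_signal(s)
  out <- gsr(s)
  m <- matrix(out$data, 150)
  expect_lt(max(abs(crossprod(g, m))) / sqrt(sum(g^2)), 1e-8)
  expect_lt(max(abs(rowMeans(m))), 1e-10)
  const <- image_stack(array(7, c(10, 2, 2)), 30)
  expect_error(gsr(const), "constant")
})

test_that("gsr recovers a local source hidden under a strong global", {
  set.seed(13)
  n <- 500
  local_src <- as.numeric(stats::filter(rnorm(n), rep(0.2, 5),
                                        circular = TRUE))
  g <- as.numeric(stats::filter(rnorm(n), rep(0.2, 5), circular = TRUE))
  # a small minority of pixels carries the local source, all carry
  # 0.8 * global, so the spatial mean is dominated by the global component
  m <- cbind(sapply(1:2, function(i) local_src + 0.8 * g),
             sapply(1:62, function(i) 0.8 * g + rnorm(n, sd = 1e-8)))
  out <- gsr(stack_from_mat(m, 8, 8))
  r <- cor(out$data[, 1, 1], local_src)
  expect_gt(r, 0.99)
})

test_that("concatenation appends frames in order and checks shapes", {
  a <- indexed_stack(nf = 30, h = 2, w = 3)
  b <- rand_stack(nf = 70, h = 2, w = 3, seed = 21)
  expect_identical(concat_stacks(list(a)), a)
  ab <- concat_stacks(list(a, b))
  expect_equal(n_frames(ab), 100L)
  expect_equal(get_frame(ab, 30), get_frame(b, 0))
  c3 <- rand_stack(nf = 10, h = 2, w = 3, seed = 22)
  expect_identical(concat_stacks(list(concat_stacks(list(a, b)), c3))$data,
                   concat_stacks(list(a, b, c3))$data)
  expect_error(concat_stacks(list(a, rand_stack(nf = 5, h = 3, w = 3))),
               "size mismatch")
  bad_fps <- rand_stack(nf = 5, h = 2, w = 3); bad_fps$fps <- 15
  expect_error(concat_stacks(list(a, bad_fps)), "fps")
})

test_that("a full session of 31 x 900-frame trials concatenates to 27900", {
  trials <- lapply(1:31, function(i) image_stack(array(i, c(900, 2, 2)), 30))
  expect_equal(n_frames(concat_stacks(trials)), 27900L)
})

test_that("stack division is elementwise with undefined zero-denominators", {
  s <- rand_stack(nf = 4, h = 3, w = 3, seed = 30)
  one <- divide_stacks(s, s)
  expect_true(all(one$data == 1))
  den <- rand_stack(nf = 4, h = 3, w = 3, seed = 31)
  den$data[2, 1, 1] <- 0
  out <- divide_stacks(s, den)
  expect_true(is.nan(out$data[2, 1, 1]))
  manual <- s$data / den$data; manual[2, 1, 1] <- NaN
  expect_identical(out$data, manual)
  expect_error(divide_stacks(s, rand_stack(nf = 5, h = 3, w = 3)),
               "shape mismatch")
})

test_that("evoked averaging shrinks noise like 1/sqrt(n_trials)", {
  ident <- rand_stack(nf = 20, h = 2, w = 2, seed = 40)
  expect_equal(evoked_average(list(ident, ident))$data, ident$data)
  a <- image_stack(array(1, c(5, 2, 2)), 30)
  b <- image_stack(array(3, c(5, 2, 2)), 30)
  expect_true(all(evoked_average(list(a, b))$data == 2))

  set.seed(41)
  resp <- sin(2 * pi * (0:99) / 50)
  trials <- lapply(1:16, function(i)
    stack_from_mat(matrix(resp + rnorm(100), 100), 1, 1))
  avg <- evoked_average(trials)
  resid_sd <- sd(avg$data[, 1, 1] - resp)
  expect_equal(resid_sd, 1 / sqrt(16), tolerance = 0.2)

  short <- rand_stack(nf = 50, h = 2, w = 2)
  expect_error(evoked_average(list(ident, short)), "lengths differ")
  expect_equal(n_frames(evoked_average(list(ident, short),
                                       truncate_to_shortest = TRUE)), 20L)
})

test_that("stdev map is the population temporal standard deviation", {
  flat <- image_stack(array(4, c(10, 3, 3)), 30)
  expect_true(all(stdev_map(flat) == 0))
  two <- stack_from_mat(matrix(c(0, 2), 2, 1), 1, 1)
  expect_equal(stdev_map(two)[1, 1], 1.0)
  s <- rand_stack(nf = 25, h = 4, w = 4, seed = 50)
  manual <- apply(s$data, c(2, 3), function(v) sqrt(mean((v - mean(v))^2)))
  expect_equal(stdev_map(s), manual)
  expect_error(stdev_map(image_stack(matrix(1, 2, 2), 30)), "2 frames")
})
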