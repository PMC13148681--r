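test_that("flow/rate alignment interpolates linearly and drops missing segments", {
  t0 <- as.POSIXct("2025-08-03 10:00:00", tz = "UTC")
  rate <- data.frame(time = t0 + c(0, 1200), rate = c(0.2, 0.4))
  flow <- data.frame(time = t0 + 600, speed_px_s = 5, direction_deg = 90,
                     missing = FALSE)
  p <- align_series(flow, rate)
  expect_equal(p$rate, 0.3)  # midpoint

  # identical timestamps: identity pairing
  flow2 <- data.frame(time = rate$time, speed_px_s = c(1, 2),
                      direction_deg = c(0, 0), missing = c(FALSE, FALSE))
  p2 <- align_series(flow2, rate)
  expect_equal(p2$rate, rate$rate)

  # missing segments are dropped from the pairing
  flow3 <- data.frame(time = t0 + seq(0, 1200, length.out = 50),
                      speed_px_s = 1, direction_deg = 0,
                      missing = rep(c(FALSE, TRUE), c(47, 3)))
  expect_equal(attr(align_series(flow3, rate), "n_pairs"), 47)

  late <- data.frame(time = t0 + 1e6, speed_px_s = 1, direction_deg = 0,
                     missing = FALSE)
  expect_error(align_series(late, rate), "overlap")
})

test_that("signed angle wraps into (-180, 180] and is idempotent", {
  expect_equal(signed_angle(45, 45), 0)
  expect_equal(signed_angle(225, 45), 180)
  expect_equal(signed_angle(315, 45), -90)
  expect_equal(signed_angle(46, 45), 1)
  # idempotent about axis 0
  a <- seq(-170, 180, by = 10)
  expect_equal(signed_angle(signed_angle(a, 0), 0), a)
})

test_that("Pearson correlation matches closed forms and flags degeneracy", {
  x <- 1:20
  r1 <- pearson_cor(x, 2 * x + 1)
  expect_equal(r1$r, 1, tolerance = 1e-12)

  set.seed(1)
  y <- rnorm(2000)
  r0 <- pearson_cor(rnorm(2000), y)
  expect_lt(abs(r0$r), 0.08)
  expect_gt(r0$p_value, 1e-4)

  # symmetry and affine invariance
  set.seed(2)
  a <- rnorm(50); b <- a + rnorm(50)
  expect_equal(pearson_cor(a, b)$r, pearson_cor(b, a)$r)
  expect_equal(pearson_cor(3 * a - 7, b)$r, pearson_cor(a, b)$r, tolerance = 1e-12)
  expect_equal(pearson_cor(-a, b)$r, -pearson_cor(a, b)$r, tolerance = 1e-12)

  dz <- pearson_cor(rep(1, 10), rnorm(10))
  expect_false(dz$defined)
  expect_error(pearson_cor(1:2, 1:2), "at least 3")
})

test_that("periodogram finds a 12-h cycle sampled at the segment cadence", {
  t_h <- seq(0, 72, by = 1 / 3)[-1]  # 20-min cadence, 3 days
  x <- sin(2 * pi * t_h / 12) + rnorm(length(t_h), sd = 0.1)
  psd <- periodogram_psd(x, cadence_min = 20)
  f_peak <- psd$frequency_per_h[which.max(psd$power)]
  df <- diff(psd$frequency_per_h[1:2])
  expect_lt(abs(f_peak - 1 / 12), df + 1e-12)
  expect_true(all(psd$power >= 0))
  expect_true(all(psd$lo95 <= psd$power & psd$power <= psd$hi95))
})

test_that("chi-squared periodogram bounds cover a white-noise spectrum at ~95%", {
  set.seed(99)
  n <- 128; sigma <- 1
  # flat true spectrum level for this normalization, estimated analytically:
  # raw periodogram ordinates of white noise average to sigma^2 (R convention)
  cover <- replicate(400, {
    psd <- periodogram_psd(rnorm(n, sd = sigma), cadence_min = 20)
    mean(psd$lo95 <= sigma^2 & sigma^2 <= psd$hi95)
  })
  expect_gt(mean(cover), 0.90)
  expect_lt(mean(cover), 0.99)
})

test_that("a constant series has no power at nonzero frequency", {
  psd <- periodogram_psd(rep(3.2, 64), cadence_min = 20)
  expect_true(all(psd$power < 1e-20))
  expect_error(periodogram_psd(c(1, 2, 3), 20), "too short")
  expect_error(periodogram_psd(c(1, NA, 3, 4, 5), 20), "gap-free")
})

test_that("flow axis estimation pools antiparallel directions", {
  dirs <- c(rnorm(50, 88, 4), rnorm(50, 268, 4)) %% 360
  ax <- estimate_flow_axis(dirs)
  expect_equal(ax, 88, tolerance = 2)
  # signed speed projects onto the axis with sign
  expect_equal(signed_speed(2, 88, 88), 2)
  expect_equal(signed_speed(2, 268, 88), -2, tolerance = 1e-12)
})
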