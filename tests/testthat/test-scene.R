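test_that("recording schedule tiles the deployment with the duty-cycle period", {
  start <- as.POSIXct("2025-08-03 00:00:00", tz = "UTC")
  # 74.33 h of 10-min-on/10-min-off recording yields 223 segments (37 h)
  sch <- generate_schedule(start, total_h = 74.33)
  expect_equal(nrow(sch), 223)
  expect_equal(sum(sch$duration_s) / 3600, 37, tolerance = 0.01)

  expect_equal(nrow(generate_schedule(start, total_h = 1)), 3)

  # no pause: contiguous segments
  cont <- generate_schedule(start, total_h = 1, on_min = 10, off_min = 0)
  expect_true(all(diff(as.numeric(cont$start)) == 600))
  expect_true(all(cont$duration_s == 600))

  expect_error(generate_schedule(start, 1, on_min = 0), "on_min")
})

test_that("scene ground truth obeys its structural invariants", {
  sc <- small_scene(seed = 5, hours = 25, frames = 4)
  tr <- sc$truth$frames
  # counts equal the length of the position lists, every frame
  for (s in seq_along(sc$segments)) {
    for (k in seq_len(4)) {
      n_truth <- tr$count[tr$segment == sc$segments[[s]]$segment_id & tr$frame == k]
      expect_equal(nrow(sc$truth$positions[[s]][[k]]), n_truth)
    }
  }
  expect_true(all(is.finite(tr$count)))
  expect_true(all(tr$area_px >= 0))
})

test_that("truth flow reverses by 180 degrees across slack water and is tide-scaled", {
  sc <- small_scene(seed = 2, hours = 25)
  tr <- sc$truth$frames
  rate <- sea_level_rate(sc$tide, smooth_window_h = 0)
  r_seg <- approx(as.numeric(rate$time), rate$rate, xout = as.numeric(tr$time))$y
  ang <- atan2(tr$v, tr$u) * 180 / pi
  rising <- ang[r_seg > 0.05]; falling <- ang[r_seg < -0.05]
  d <- abs(((median(rising) - median(falling)) %% 360))
  expect_equal(min(d, 360 - d), 180, tolerance = 1e-6)
  # speed proportional to |rate| with the configured gain
  spd <- sqrt(tr$u^2 + tr$v^2)
  expect_equal(spd, sc$config$flow_gain * abs(r_seg), tolerance = 1e-6)
})

test_that("flow_gain = 0 freezes the imposed flow and zero density empties the scene", {
  tide <- generate_tide(25 * 3600)
  sch <- generate_schedule(min(tide$time), total_h = 2)
  cfg0 <- scene_config(width = 48, height = 32, particle_density = 10,
                       frames_per_segment = 3, flow_gain = 0, seed = 1)
  sc0 <- generate_scene(cfg0, tide, sch)
  expect_true(all(sc0$truth$frames$u == 0 & sc0$truth$frames$v == 0))

  cfg_empty <- scene_config(width = 48, height = 32, particle_density = 0,
                            frames_per_segment = 3, seed = 1)
  sce <- generate_scene(cfg_empty, tide, sch)
  expect_true(all(sce$truth$frames$count == 0))
  expect_true(all(sce$truth$frames$area_px == 0))
})

test_that("per-frame particle counts are Poisson around the configured density", {
  tide <- generate_tide(25 * 3600)
  sch <- generate_schedule(min(tide$time), total_h = 20)  # 60 segments
  cfg <- scene_config(width = 160, height = 120, particle_density = 85,
                      frames_per_segment = 1, seed = 11)
  sc <- generate_scene(cfg, tide, sch)
  counts <- sc$truth$frames$count
  n <- length(counts)
  expect_lt(abs(mean(counts) - 85), 3 * sqrt(85) / sqrt(n))
})

test_that("scenes are bit-identical across runs for a fixed seed", {
  a <- small_scene(seed = 9, hours = 25, frames = 2)
  b <- small_scene(seed = 9, hours = 25, frames = 2)
  expect_identical(a$segments[[1]]$frames, b$segments[[1]]$frames)
  expect_identical(a$truth$frames, b$truth$frames)
})

test_that("static background elements are identical in every frame", {
  sc <- small_scene(seed = 3, hours = 25, frames = 4, density = 0, noise_sd = 0)
  st <- sc$segments[[1]]
  for (k in 2:4) expect_identical(st$frames[[k]], st$frames[[1]])
  # the static mask marks bright background structure
  expect_gt(sum(sc$truth$static_mask), 0)
  red <- st$frames[[1]][, , 1]
  expect_gt(mean(red[sc$truth$static_mask]), mean(red[!sc$truth$static_mask]))
})

test_that("anomaly injection modifies exactly the specified frames", {
  sc <- small_scene(seed = 4, hours = 25, frames = 40)
  stack <- sc$segments[[1]]

  # no specs: bit-identical frames
  clean <- inject_anomalies(stack, list())
  expect_identical(clean$stack$frames, stack$frames)
  expect_equal(nrow(clean$log), 0)

  # first-frame spike raises frame 1's mean by ~ the magnitude
  spiked <- inject_anomalies(stack, list(list(type = "first_frame_spike",
                                              magnitude = 80)))
  d1 <- mean(spiked$stack$frames[[1]]) - mean(stack$frames[[1]])
  expect_equal(d1, 80, tolerance = 8)  # slight loss to the 255 ceiling
  expect_identical(spiked$stack$frames[[2]], stack$frames[[2]])

  # lens blob adds its pixel area for exactly its duration
  blob <- inject_anomalies(stack, list(list(type = "lens_blob", area_px = 400,
                                            onset = 10, duration = 15)))
  expect_equal(blob$log$onset_frame, 10L)
  expect_false(identical(blob$stack$frames[[10]], stack$frames[[10]]))
  expect_false(identical(blob$stack$frames[[24]], stack$frames[[24]]))
  expect_identical(blob$stack$frames[[9]], stack$frames[[9]])
  expect_identical(blob$stack$frames[[25]], stack$frames[[25]])

  expect_error(inject_anomalies(stack, list(list(type = "lens_blob", area_px = 10,
                                                 onset = 39, duration = 10))),
               "out of range")
})

test_that("test audio is a deterministic tone-plus-noise waveform", {
  # single tone, no noise: peak equals the tone amplitude
  x <- generate_test_audio(0.1, fs = 96000, tones = list(c(1000, 0.5)))
  expect_equal(max(abs(x)), 0.5, tolerance = 1e-6)

  # empty tones, zero noise: silence
  z <- generate_test_audio(0.1, fs = 8000)
  expect_true(all(z == 0))

  # both study tones fit under the 48 kHz Nyquist at 96 kHz
  xx <- generate_test_audio(0.05, fs = 96000,
                            tones = list(c(1000, 0.3), c(30000, 0.1)))
  expect_true(all(is.finite(xx)))
  expect_error(generate_test_audio(0.05, fs = 96000, tones = list(c(48000, 1))),
               "Nyquist")

  a <- generate_test_audio(0.1, fs = 8000, noise_sd = 0.1, seed = 7)
  b <- generate_test_audio(0.1, fs = 8000, noise_sd = 0.1, seed = 7)
  expect_identical(as.numeric(a), as.numeric(b))
})

test_that("sensor log tracks the tide around the bottom depth", {
  tide <- generate_tide(25 * 3600, semidiurnal_amp = 1.5)
  log <- generate_sensor_log(tide)
  expect_equal(nrow(log), nrow(tide))
  expect_equal(mean(log$depth_m), 260, tolerance = 0.2)
  expect_equal(diff(range(log$depth_m)), 3, tolerance = 0.01)
})
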