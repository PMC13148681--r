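test_that("temporal-median background keeps static structure and drops movers", {
  # all-identical frames: background equals the frame
  st <- constant_stack(6, rgb = c(37, 0, 0))
  bg <- estimate_background(st, window = 5)
  expect_true(all(bg$background == 37))

  # a pixel bright in 1 of 3 frames is excluded by the median
  fr <- lapply(1:3, function(i) {
    a <- array(0, c(8, 8, 3)); if (i == 2) a[4, 4, 1] <- 255; a
  })
  st3 <- frame_stack(fr, 30, Sys.time())
  bg3 <- estimate_background(st3, window = 3, exclude_first = FALSE)
  expect_equal(bg3$background[4, 4], 0)

  # synthetic scene: the static line/end-cap stays in the background,
  # moving discs leave no residual above threshold at static pixels
  sc <- small_scene(seed = 12, hours = 25, frames = 9, density = 10)
  seg <- sc$segments[[3]]
  bgs <- estimate_background(seg, window = 8)
  static <- sc$truth$static_mask
  bg_red <- bgs$background
  expect_gt(mean(bg_red[static]), mean(bg_red[!static]) + 20)
  resid <- pmax(seg$frames[[5]][, , 1] - bg_red, 0)
  expect_lt(mean(resid[static] > 30), 0.02)

  expect_error(estimate_background(st, window = 2), ">= 3")
  expect_warning(estimate_background(st, window = 50), "clipped")
})

test_that("frame quantification recovers exact counts and areas in closed form", {
  h <- 480; w <- 640
  bg <- zero_background(h, w)
  # frame identical to background: nothing detected
  zero <- array(0, c(h, w, 3))
  s0 <- quantify_frame(zero, bg, threshold_policy = "fixed", fixed_threshold = 10)
  expect_equal(s0$count, 0)
  expect_equal(s0$area_fraction, 0)

  # one 10x10 bright square: count 1, A = 100 / 307200
  sq <- zero; sq[101:110, 201:210, 1] <- 200
  s1 <- quantify_frame(sq, bg, threshold_policy = "fixed", fixed_threshold = 50)
  expect_equal(s1$count, 1)
  expect_equal(s1$area_fraction, 100 / (640 * 480))
})

test_that("count and area match the flood-fill oracle on small frames", {
  set.seed(31)
  for (rep in 1:8) {
    h <- sample(16:32, 1); w <- sample(16:32, 1)
    fr <- array(0, c(h, w, 3))
    fr[, , 1] <- sample(c(0, 0, 0, 80, 200), h * w, replace = TRUE)
    bg <- zero_background(h, w)
    got <- quantify_frame(fr, bg, threshold_policy = "fixed",
                          fixed_threshold = 50, min_blob_px = 2)
    oracle <- floodfill_components(fr[, , 1] > 50, min_px = 2)
    expect_equal(got$count, oracle$count)
    expect_equal(got$area_fraction, oracle$area / (h * w))
  }
})

test_that("stats are invariant to a constant offset and monotone in particles", {
  set.seed(8)
  h <- 64; w <- 64
  centers <- cbind(x = c(15, 40, 52), y = c(20, 45, 12))
  img <- render_particles(h, w, centers, sigma = 1.5, amp = 220)
  fr <- array(0, c(h, w, 3)); fr[, , 1] <- img
  bg <- zero_background(h, w)
  base <- quantify_frame(fr, bg, threshold_policy = "fixed", fixed_threshold = 60)
  expect_equal(base$count, 3)

  # add the same constant to frame and background: residual unchanged
  fr2 <- fr; fr2[, , 1] <- fr2[, , 1] + 40
  bg2 <- bg; bg2$background <- bg2$background + 40
  shifted <- quantify_frame(fr2, bg2, threshold_policy = "fixed", fixed_threshold = 60)
  expect_equal(shifted$count, base$count)
  expect_equal(shifted$area_fraction, base$area_fraction)

  # one extra well-separated particle: count + 1, larger area
  fr3 <- fr; fr3[, , 1] <- fr3[, , 1] +
    render_particles(h, w, cbind(x = 30, y = 58), sigma = 1.5, amp = 220)
  extra <- quantify_frame(fr3, bg, threshold_policy = "fixed", fixed_threshold = 60)
  expect_equal(extra$count, base$count + 1)
  expect_gt(extra$area_fraction, base$area_fraction)
})

test_that("counts recover scene truth on well-separated synthetic scenes", {
  # low density so discs are separated by >> 2 radii almost surely
  sc <- small_scene(seed = 21, hours = 25, width = 96, height = 72,
                    density = 5, frames = 10, radius = c(1.5, 2.5),
                    noise_sd = 2)
  err <- c(); afrac_meas <- c(); afrac_truth <- c()
  for (s in seq_along(sc$segments)) {
    seg <- sc$segments[[s]]
    st <- quantify_segment(seg, background_window = 9)
    tr <- sc$truth$frames[sc$truth$frames$segment == seg$segment_id, ]
    err <- c(err, st$count - tr$count)
    afrac_meas <- c(afrac_meas, st$area_fraction)
    afrac_truth <- c(afrac_truth, tr$area_px / (96 * 72))
  }
  expect_equal(median(err), 0)
  # total detected area tracks the truth foreground fraction
  keep <- afrac_truth > 0
  ratio <- sum(afrac_meas[keep]) / sum(afrac_truth[keep])
  expect_gt(ratio, 0.8); expect_lt(ratio, 1.2)
})

test_that("mean color is the per-channel arithmetic mean", {
  fr <- array(rep(c(200, 10, 5), each = 24 * 32), c(24, 32, 3))
  expect_equal(unname(mean_color(fr)), c(200, 10, 5))

  # half-black/half-white frame
  bw <- array(0, c(10, 10, 3)); bw[1:5, , ] <- 255
  expect_equal(unname(mean_color(bw)), rep(127.5, 3))

  # the red-lit synthetic seafloor is red-dominant
  sc <- small_scene(seed = 13, hours = 25, frames = 2)
  m <- mean_color(sc$segments[[1]]$frames[[1]])
  expect_gt(m["r"], 5 * m["g"])
  expect_gt(m["r"], 5 * m["b"])

  expect_error(mean_color(matrix(0, 4, 4)), "3-channel")
})

test_that("sliding median has the documented kernel and robustness", {
  # 3 h window at 20-min cadence = 9 samples
  x <- c(rep(1, 20)); x[10] <- 50
  sm <- sliding_median(x, window_h = 3, cadence_min = 20)
  expect_true(all(sm == 1))
  expect_identical(sliding_median(rep(2, 15), 3, 20), rep(2, 15))
  expect_warning(out <- sliding_median(1:5, window_h = 0.1, cadence_min = 20),
                 "unchanged")
  expect_identical(out, 1:5)
  # NA samples (missing segments) are tolerated
  y <- c(1, 1, NA, 1, 1, 9, 1, 1)
  expect_true(all(is.finite(sliding_median(y, 3, 20))))
})
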