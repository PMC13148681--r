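test_that("uniform integer shifts are recovered exactly", {
  for (shift in list(c(3, 0), c(0, -2), c(-4, 5))) {
    p <- shifted_pair(96, 96, n = 60, shift = shift, seed = shift[1] + 10)
    f <- piv_pair(p$a, p$b, window_px = 32, passes = 1)
    expect_true(any(f$valid))
    expect_equal(unname(f$u[f$valid]), rep(shift[1], sum(f$valid)), tolerance = 1e-6)
    expect_equal(unname(f$v[f$valid]), rep(shift[2], sum(f$valid)), tolerance = 1e-6)
  }
})

test_that("subpixel shifts are recovered within 0.1 px per component", {
  p <- shifted_pair(128, 128, n = 45, shift = c(2.5, -1.25), seed = 2, sigma = 1)
  f <- validate_vectors(piv_pair(p$a, p$b, window_px = 32, passes = 1))
  expect_lt(abs(mean(f$u[f$valid]) - 2.5), 0.1)
  expect_lt(abs(mean(f$v[f$valid]) - (-1.25)), 0.1)
})

test_that("identical frames give a zero field; degenerate inputs are rejected", {
  p <- shifted_pair(64, 64, n = 20, shift = c(0, 0), seed = 3)
  f <- piv_pair(p$a, p$a, window_px = 32, passes = 1)
  expect_true(all(abs(f$u[f$valid]) < 1e-9))
  expect_true(all(abs(f$v[f$valid]) < 1e-9))

  # all-zero windows carry no signal: marked invalid, not zero
  z <- matrix(0, 64, 64)
  fz <- piv_pair(z, z, window_px = 32, passes = 1)
  expect_false(any(fz$valid))

  expect_error(piv_pair(matrix(0, 20, 20), matrix(0, 20, 20), window_px = 32),
               "larger than the image")
  expect_error(piv_pair(p$a, p$a, window_px = 8), ">= 16")
  expect_error(piv_pair(p$a, matrix(0, 32, 64)), "same shape")
})

test_that("multi-pass refinement handles displacements beyond the final window", {
  p <- shifted_pair(128, 128, n = 40, shift = c(10, 0), seed = 4, sigma = 2)
  f2 <- piv_pair(p$a, p$b, window_px = 64, passes = 2)
  expect_equal(mean(f2$u[f2$valid]), 10, tolerance = 0.1)
  expect_equal(mean(f2$v[f2$valid]), 0, tolerance = 0.1)
  expect_equal(f2$window_px, 32)
})

test_that("normalized-median validation invalidates exactly the outlier", {
  # uniform field: nothing invalidated
  mkfield <- function(u) {
    structure(list(x = matrix(rep(1:5 * 16, each = 5), 5, 5, byrow = TRUE),
                   y = matrix(rep(1:5 * 16, 5), 5, 5),
                   u = u, v = matrix(0, 5, 5),
                   valid = matrix(TRUE, 5, 5),
                   peak_ratio = matrix(2, 5, 5), window_px = 32L),
              class = "vector_field")
  }
  uni <- validate_vectors(mkfield(matrix(1, 5, 5)))
  expect_true(all(uni$valid))

  # one vector perturbed by 20 px: normalized residual = 20 / eps = 200
  u <- matrix(1, 5, 5); u[3, 3] <- 21
  pert <- validate_vectors(mkfield(u), eps = 0.1, residual_threshold = 2)
  expect_false(pert$valid[3, 3])
  expect_equal(sum(!pert$valid), 1)

  # all-invalid input stays all-invalid
  dead <- mkfield(matrix(1, 5, 5)); dead$valid[] <- FALSE
  expect_false(any(validate_vectors(dead)$valid))
})

test_that("dominant flow averages magnitudes linearly and directions circularly", {
  f <- structure(list(u = matrix(1, 2, 2), v = matrix(0, 2, 2),
                      valid = matrix(TRUE, 2, 2),
                      x = matrix(0, 2, 2), y = matrix(0, 2, 2),
                      peak_ratio = matrix(2, 2, 2), window_px = 32L),
                 class = "vector_field")
  d <- dominant_flow(f, fps = 30)
  expect_equal(d$speed_px_s, 30)
  expect_equal(d$direction_deg, 0)

  # 350 and 10 degrees average to 0, never 180
  th <- c(350, 10) * pi / 180
  f2 <- f; f2$u <- matrix(cos(th), 1); f2$v <- matrix(-sin(th), 1)
  f2$valid <- matrix(TRUE, 1, 2)
  d2 <- dominant_flow(f2, fps = 1)
  expect_lt(min(d2$direction_deg, 360 - d2$direction_deg), 1e-6)

  # zero valid vectors: missing, not zero
  f3 <- f; f3$valid[] <- FALSE
  d3 <- dominant_flow(f3, fps = 30)
  expect_true(d3$missing)
  expect_true(is.na(d3$speed_px_s))

  # negated field points exactly 180 degrees away
  f4 <- f; f4$u <- -f$u; f4$v <- -f$v
  d4 <- dominant_flow(f4, fps = 30)
  expect_equal((d4$direction_deg - d$direction_deg) %% 360, 180)
})

test_that("rotating both frames by 90 degrees rotates the dominant direction by 90", {
  p <- shifted_pair(96, 96, n = 30, shift = c(3, 1), seed = 5)
  f <- piv_pair(p$a, p$b, window_px = 32, passes = 1)
  d <- dominant_flow(f, fps = 1)$direction_deg
  fr <- piv_pair(rot90_ccw(p$a), rot90_ccw(p$b), window_px = 32, passes = 1)
  dr <- dominant_flow(fr, fps = 1)$direction_deg
  expect_equal((dr - d) %% 360, 90, tolerance = 0.5)
})

test_that("segment-level PIV recovers the imposed tide-driven flow", {
  sc <- small_scene(seed = 22, hours = 25, width = 96, height = 72,
                    density = 20, frames = 10)
  tr <- sc$truth$frames
  # pick the segment with the strongest imposed flow
  spd <- tapply(sqrt(tr$u^2 + tr$v^2), tr$segment, mean)
  seg_id <- names(which.max(spd))
  seg <- sc$segments[[which(vapply(sc$segments, `[[`, "", "segment_id") == seg_id)]]
  flow <- piv_segment(seg, n_frames = 10, window_px = 32, passes = 1)
  expect_false(flow$missing)
  tru <- tr[tr$segment == seg_id, ]
  true_dir <- (atan2(mean(tru$v), mean(tru$u)) * 180 / pi) %% 360
  true_spd <- mean(sqrt(tru$u^2 + tru$v^2)) * seg$fps
  dd <- abs((flow$direction_deg - true_dir + 180) %% 360 - 180)
  expect_lt(dd, 5)
  expect_lt(abs(flow$speed_px_s - true_spd) / true_spd, 0.1)
})
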