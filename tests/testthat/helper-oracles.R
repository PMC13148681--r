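# Independent oracles and small fixture builders used across tests.

# Exhaustive 8-connected component enumeration by breadth-first flood fill.
# Pure R, independent of the package's labelling path. Returns a list with
# the component count and total foreground area over components of at
# least min_px pixels.
floodfill_components <- function(bw, min_px = 1L) {
  h <- nrow(bw); w <- ncol(bw)
  seen <- matrix(FALSE, h, w)
  sizes <- integer(0)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (!bw[r, c] || seen[r, c]) next
    queue <- matrix(c(r, c), 1, 2)
    seen[r, c] <- TRUE
    size <- 0L
    while (nrow(queue) > 0L) {
      p <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
      size <- size + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1] + dr; cc <- p[2] + dc
        if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
            bw[rr, cc] && !seen[rr, cc]) {
          seen[rr, cc] <- TRUE
          queue <- rbind(queue, c(rr, cc))
        }
      }
    }
    sizes <- c(sizes, size)
  }
  keep <- sizes >= min_px
  list(count = sum(keep), area = sum(sizes[keep]))
}

# Render Gaussian particles at continuous (x = col, y = row) centers onto a
# zero background; no wrap-around (keep centers away from the edges).
# Independent of the package's scene renderer.
render_particles <- function(h, w, centers, sigma = 1.5, amp = 200) {
  img <- matrix(0, h, w)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (i in seq_len(nrow(centers))) {
    img <- img + amp * exp(-((rows - centers[i, 2])^2 +
                             (cols - centers[i, 1])^2) / (2 * sigma^2))
  }
  img
}

# A frame pair with an exact imposed displacement (u right, v down).
shifted_pair <- function(h = 96, w = 96, n = 60, shift = c(3, 0), seed = 1,
                         sigma = 1.2) {
  set.seed(seed)
  margin <- 12
  centers <- cbind(x = runif(n, margin, w - margin),
                   y = runif(n, margin, h - margin))
  a <- render_particles(h, w, centers, sigma = sigma)
  b <- render_particles(h, w, cbind(centers[, 1] + shift[1],
                                    centers[, 2] + shift[2]), sigma = sigma)
  list(a = a, b = b)
}

# 90-degree counterclockwise rotation in the y-up display convention.
rot90_ccw <- function(m) t(m)[ncol(m):1, ]

# A zero background model matching a given frame shape.
zero_background <- function(h, w, channel = "red") {
  structure(list(background = matrix(0, h, w), method = "temporal_median",
                 window = 3L, channel = channel),
            class = "background_model")
}

# A constant-color frame stack.
constant_stack <- function(n, h = 24, w = 32, rgb = c(10, 0, 0), fps = 30) {
  fr <- lapply(seq_len(n), function(i)
    array(rep(rgb, each = h * w), c(h, w, 3)))
  frame_stack(fr, fps = fps,
              start_time = as.POSIXct("2025-08-03 00:00:00", tz = "UTC"),
              segment_id = "const")
}

# Small tide + scene bundle used by several tests. Study-shaped conditions
# (M2 tide, 20-min duty cycle) at reduced image scale.
small_scene <- function(seed = 1, hours = 25, width = 64, height = 48,
                        density = 15, frames = 5, flow_gain = 4,
                        radius = c(1, 3), noise_sd = 3) {
  tide <- generate_tide(duration = hours * 3600, semidiurnal_amp = 1.5,
                        seed = seed)
  cfg <- scene_config(width = width, height = height,
                      particle_density = density, particle_radius = radius,
                      frames_per_segment = frames, flow_gain = flow_gain,
                      noise_sd = noise_sd, seed = seed)
  sch <- generate_schedule(min(tide$time), total_h = hours)
  sc <- generate_scene(cfg, tide, sch)
  c(sc, list(tide = tide, config = cfg))
}
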