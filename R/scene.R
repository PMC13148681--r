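#' Configuration for the synthetic seafloor scene generator
#'
#' Defaults emulate the study deployment: VGA frames (640 x 480) at 30 fps,
#' red-LED illumination (red channel dominant, green/blue near zero), about
#' 85 suspended particles per frame drifting with the tidal current, a
#' static mooring line and a reflective recorder end-cap in every frame.
#'
#' @param width,height frame size in px.
#' @param fps frames per second.
#' @param frames_per_segment number of frames rendered per scheduled segment
#'   (the burst analysed per file; rendering full 10-minute files is never
#'   needed for the quantities this package computes).
#' @param particle_density expected particle count per frame (Poisson mean).
#' @param particle_radius length-2 range of disc radii, px.
#' @param particle_brightness length-2 range of peak brightness, 0--255.
#' @param background_level red-channel background intensity (<= 20).
#' @param flow_gain px/frame of particle drift per m/h of sea-level rate.
#' @param flow_axis_deg geographic axis the tidal current follows, in image
#'   coordinates (degrees CCW from +x with y up). 90 means flood flow toward
#'   the image top.
#' @param jitter_sd per-particle, per-frame random walk sd in px.
#' @param noise_sd additive sensor noise sd, intensity units.
#' @param fibers also draw elongated fiber-like particles (off by default).
#' @param background_elements draw the static mooring line and end-cap.
#' @param seed integer RNG seed; a fixed seed gives bit-identical scenes.
#' @return a `scene_config` list.
#' @export
scene_config <- function(width = 640, height = 480, fps = 30,
                         frames_per_segment = 12,
                         particle_density = 85,
                         particle_radius = c(1, 4),
                         particle_brightness = c(80, 255),
                         background_level = 12,
                         flow_gain = 4,
                         flow_axis_deg = 90,
                         jitter_sd = 0.5,
                         noise_sd = 3,
                         fibers = FALSE,
                         background_elements = TRUE,
                         seed = 1L) {
  stopifnot_scalar(width, "width", positive = TRUE)
  stopifnot_scalar(height, "height", positive = TRUE)
  stopifnot_scalar(fps, "fps", positive = TRUE)
  if (particle_density < 0) stop("'particle_density' must be >= 0", call. = FALSE)
  if (any(particle_brightness < 0 | particle_brightness > 255))
    stop("'particle_brightness' must lie in [0, 255]", call. = FALSE)
  structure(list(width = as.integer(width), height = as.integer(height),
                 fps = fps, frames_per_segment = as.integer(frames_per_segment),
                 particle_density = particle_density,
                 particle_radius = particle_radius,
                 particle_brightness = particle_brightness,
                 background_level = background_level,
                 flow_gain = flow_gain, flow_axis_deg = flow_axis_deg,
                 jitter_sd = jitter_sd, noise_sd = noise_sd,
                 fibers = fibers,
                 background_elements = background_elements,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Recording schedule of a duty-cycled camera
#'
#' Segments tile the deployment with period `on + off` minutes: 10 minutes
#' of video every 20 minutes reproduces the deployment's 223 files over
#' 74.33 h (37 h of footage).
#'
#' @param start POSIXct UTC start of the deployment.
#' @param total_h total deployment span in hours.
#' @param on_min,off_min recording and pause durations in minutes (> 0 and
#'   >= 0 respectively).
#' @return data.frame with `segment_id`, `start` (POSIXct UTC), `duration_s`.
#' @export
generate_schedule <- function(start, total_h, on_min = 10, off_min = 10) {
  stopifnot_scalar(total_h, "total_h", positive = TRUE)
  if (on_min <= 0 || off_min < 0)
    stop("'on_min' must be > 0 and 'off_min' >= 0", call. = FALSE)
  start <- as_utc(start)
  period <- on_min + off_min
  total_min <- total_h * 60
  starts_min <- seq(0, by = period, length.out = ceiling(total_min / period))
  starts_min <- starts_min[starts_min < total_min]
  dur_s <- pmin(on_min, total_min - starts_min) * 60
  data.frame(segment_id = sprintf("seg_%04d", seq_along(starts_min)),
             start = start + starts_min * 60,
             duration_s = dur_s)
}

# H x W x 3 static background: red-lit darkness, diagonal mooring line,
# bright elliptical recorder end-cap. Identical in every frame.
scene_background <- function(config) {
  h <- config$height; w <- config$width
  img <- array(0, c(h, w, 3))
  img[, , 1] <- config$background_level
  img[, , 2] <- 2
  img[, , 3] <- 2
  mask <- matrix(FALSE, h, w)
  if (isTRUE(config$background_elements)) {
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    # diagonal mooring rope, ~2 px wide
    line <- abs(rows - cols * h / w) < 2
    # reflective end-cap: bright ellipse upper-right
    cy <- 0.22 * h; cx <- 0.78 * w
    ell <- ((rows - cy) / (0.06 * h))^2 + ((cols - cx) / (0.06 * w))^2 <= 1
    img[, , 1][line] <- 70
    img[, , 1][ell] <- 150
    img[, , 2][ell] <- 12
    img[, , 3][ell] <- 10
    mask <- line | ell
  }
  list(img = img, static_mask = mask)
}

# Add one Gaussian-profile disc at (x, y) (px, 1-based continuous, x = col,
# y = row) with wrap-around at the frame edges. Returns the modified channel.
draw_disc <- function(chan, x, y, radius, brightness) {
  h <- nrow(chan); w <- ncol(chan)
  sigma <- radius / 1.5
  ext <- ceiling(3 * sigma)
  rr <- (floor(y) - ext):(floor(y) + ext)
  cc <- (floor(x) - ext):(floor(x) + ext)
  ri <- ((rr - 1) %% h) + 1
  ci <- ((cc - 1) %% w) + 1
  dy <- rr - y; dx <- cc - x
  g <- brightness * exp(-(outer(dy^2, dx^2, "+")) / (2 * sigma^2))
  chan[ri, ci] <- chan[ri, ci] + g
  chan
}

# Pixels within `radius` of (x, y), wrap-around; used for ground-truth
# foreground area.
disc_mask <- function(mask, x, y, radius) {
  h <- nrow(mask); w <- ncol(mask)
  ext <- ceiling(radius)
  rr <- (floor(y) - ext):(floor(y) + ext)
  cc <- (floor(x) - ext):(floor(x) + ext)
  ri <- ((rr - 1) %% h) + 1
  ci <- ((cc - 1) %% w) + 1
  dd <- outer((rr - y)^2, (cc - x)^2, "+") <= radius^2
  mask[ri, ci] <- mask[ri, ci] | dd
  mask
}

#' Generate a tide-driven synthetic particle scene with ground truth
#'
#' Renders duty-cycled video segments of drifting bright particles on a
#' dark red-lit background. Each frame's uniform drift is
#' `flow_gain * rate(t)` px/frame along `flow_axis_deg`, so the particle
#' flow reverses direction at slack water and its speed scales with the
#' sea-level rate; independent per-particle jitter is superimposed.
#' Particle count per segment is Poisson(`particle_density`); particles
#' wrap at the frame boundary, holding the expected density. Every imposed
#' value is recorded in the returned ground truth.
#'
#' @param config a [scene_config()].
#' @param tide a `tide_series` spanning the schedule.
#' @param schedule data.frame from [generate_schedule()]; default one
#'   10-min-on/10-min-off schedule across the tide span.
#' @return list with `segments` (list of `frame_stack`) and `truth`
#'   (`scene_truth`: per-frame data.frame `frames` with count, imposed
#'   (u, v) px/frame (y up), true foreground area px^2; `positions`;
#'   `static_mask`; `anomalies` log, empty here).
#' @export
generate_scene <- function(config, tide, schedule = NULL) {
  stopifnot(inherits(config, "scene_config"))
  if (is.null(schedule)) {
    span_h <- as.numeric(difftime(max(tide$time), min(tide$time), units = "hours"))
    schedule <- generate_schedule(min(tide$time), total_h = span_h)
  }
  t_lo <- min(as.numeric(tide$time)); t_hi <- max(as.numeric(tide$time))
  seg_t <- as.numeric(schedule$start)
  if (any(seg_t < t_lo - 1) || any(seg_t > t_hi + 1))
    stop("tide series does not span the recording schedule", call. = FALSE)
  rate <- sea_level_rate(tide, smooth_window_h = 0)
  rate_at <- function(tt) stats::approx(as.numeric(rate$time), rate$rate,
                                        xout = tt, rule = 2)$y
  bg <- scene_background(config)
  axis_rad <- deg2rad(config$flow_axis_deg)
  nseg <- nrow(schedule)
  nfr <- config$frames_per_segment
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)

  segments <- vector("list", nseg)
  truth_rows <- vector("list", nseg)
  positions <- vector("list", nseg)
  for (s in seq_len(nseg)) {
    set.seed(config$seed + 7919L * s)
    n <- stats::rpois(1, config$particle_density)
    px <- stats::runif(n, 0, config$width)
    py <- stats::runif(n, 0, config$height)
    pr <- stats::runif(n, config$particle_radius[1], config$particle_radius[2])
    pb <- stats::runif(n, config$particle_brightness[1], config$particle_brightness[2])
    is_fiber <- if (isTRUE(config$fibers)) stats::runif(n) < 0.15 else rep(FALSE, n)
    frames <- vector("list", nfr)
    seg_pos <- vector("list", nfr)
    rows <- matrix(NA_real_, nfr, 6)
    t0 <- as.numeric(schedule$start[s])
    for (k in seq_len(nfr)) {
      tt <- t0 + (k - 1) / config$fps
      r_mh <- rate_at(tt)
      # px/frame along the flow axis, y up; image rows increase downward
      u <- config$flow_gain * r_mh * cos(axis_rad)
      v <- config$flow_gain * r_mh * sin(axis_rad)
      if (k > 1L) {
        px <- (px + u + stats::rnorm(n, sd = config$jitter_sd)) %% config$width
        py <- (py - v + stats::rnorm(n, sd = config$jitter_sd)) %% config$height
      }
      red <- bg$img[, , 1]
      mask <- matrix(FALSE, config$height, config$width)
      if (n > 0) for (i in seq_len(n)) {
        if (is_fiber[i]) {
          # fiber: short chain of overlapping discs along a random direction
          th <- stats::runif(1, 0, pi)
          for (m in -2:2) {
            red <- draw_disc(red, px[i] + m * pr[i] * cos(th),
                             py[i] + m * pr[i] * sin(th), pr[i] * 0.7, pb[i])
          }
          mask <- disc_mask(mask, px[i], py[i], pr[i] * 2)
        } else {
          red <- draw_disc(red, px[i], py[i], pr[i], pb[i])
          mask <- disc_mask(mask, px[i], py[i], pr[i])
        }
      }
      img <- bg$img
      img[, , 1] <- red
      if (config$noise_sd > 0)
        img <- img + array(stats::rnorm(length(img), sd = config$noise_sd), dim(img))
      frames[[k]] <- round(pmin(pmax(img, 0), 255))
      seg_pos[[k]] <- cbind(x = px, y = py)
      truth_area <- sum(mask & !bg$static_mask)
      rows[k, ] <- c(s, k, n, u, v, truth_area)
    }
    tt_all <- t0 + (seq_len(nfr) - 1) / config$fps
    truth_rows[[s]] <- data.frame(
      segment = schedule$segment_id[s], frame = seq_len(nfr),
      time = as_utc(tt_all),
      count = rows[, 3], u = rows[, 4], v = rows[, 5], area_px = rows[, 6])
    positions[[s]] <- seg_pos
    segments[[s]] <- frame_stack(frames, fps = config$fps,
                                 start_time = schedule$start[s],
                                 segment_id = schedule$segment_id[s])
  }
  truth <- structure(list(frames = do.call(rbind, truth_rows),
                          positions = positions,
                          static_mask = bg$static_mask,
                          anomalies = data.frame(segment = character(),
                                                 type = character(),
                                                 onset_frame = integer(),
                                                 duration_frames = integer(),
                                                 magnitude = numeric())),
                     class = "scene_truth")
  list(segments = segments, truth = truth, schedule = schedule)
}

#' Inject transient lens/camera anomalies into a segment
#'
#' Emulates the three anomaly types seen in fixed-camera deployments:
#' a global brightness spike on the first frame (camera power-on), a large
#' static bright region from an organism attached to the lens, and a
#' gradual diffuse intensity ramp from sediment glow.
#'
#' @param stack a `frame_stack`.
#' @param specs list of anomaly specs, each a list with `type` one of
#'   `"first_frame_spike"` (`magnitude` intensity units),
#'   `"lens_blob"` (`area_px`, `onset`, `duration`, optional `x`, `y`),
#'   `"sediment_glow"` (`onset`, `duration`, `max_intensity`).
#'   Frames are 1-based; onset + duration must stay inside the segment.
#' @return list with the modified `stack` and a `log` data.frame
#'   (`type`, `onset_frame`, `duration_frames`, `magnitude`).
#' @export
inject_anomalies <- function(stack, specs) {
  n <- length(stack$frames)
  h <- dim(stack$frames[[1]])[1]; w <- dim(stack$frames[[1]])[2]
  log <- list()
  frames <- stack$frames
  for (sp in specs) {
    type <- sp$type
    if (identical(type, "first_frame_spike")) {
      mag <- if (is.null(sp$magnitude)) 80 else sp$magnitude
      frames[[1]] <- pmin(frames[[1]] + mag, 255)
      log[[length(log) + 1L]] <- data.frame(type = type, onset_frame = 1L,
                                            duration_frames = 1L, magnitude = mag)
    } else if (identical(type, "lens_blob")) {
      onset <- sp$onset; dur <- sp$duration
      if (onset < 1 || onset + dur - 1 > n)
        stop("lens_blob frames out of range", call. = FALSE)
      area <- sp$area_px
      rad <- sqrt(area / pi)
      cx <- if (is.null(sp$x)) w * 0.4 else sp$x
      cy <- if (is.null(sp$y)) h * 0.6 else sp$y
      rows <- matrix(seq_len(h), h, w); cols <- matrix(seq_len(w), h, w, byrow = TRUE)
      blob <- (rows - cy)^2 + (cols - cx)^2 <= rad^2
      for (k in onset:(onset + dur - 1L)) {
        ch <- frames[[k]][, , 1]; ch[blob] <- pmin(ch[blob] + 160, 255)
        frames[[k]][, , 1] <- ch
      }
      log[[length(log) + 1L]] <- data.frame(type = type, onset_frame = as.integer(onset),
                                            duration_frames = as.integer(dur),
                                            magnitude = sum(blob))
    } else if (identical(type, "sediment_glow")) {
      onset <- sp$onset; dur <- sp$duration
      if (onset < 1 || onset + dur - 1 > n)
        stop("sediment_glow frames out of range", call. = FALSE)
      maxi <- if (is.null(sp$max_intensity)) 40 else sp$max_intensity
      rows <- matrix(seq_len(h), h, w); cols <- matrix(seq_len(w), h, w, byrow = TRUE)
      # wide diffuse profile centered low in the frame
      prof <- exp(-(((rows - 0.8 * h) / (0.5 * h))^2 + ((cols - 0.5 * w) / (0.6 * w))^2))
      for (k in onset:(onset + dur - 1L)) {
        ramp <- maxi * (k - onset + 1) / dur
        frames[[k]][, , 1] <- pmin(frames[[k]][, , 1] + ramp * prof, 255)
      }
      log[[length(log) + 1L]] <- data.frame(type = type, onset_frame = as.integer(onset),
                                            duration_frames = as.integer(dur),
                                            magnitude = maxi)
    } else stop(sprintf("unknown anomaly type '%s'", type), call. = FALSE)
  }
  out <- stack
  out$frames <- frames
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(type = character(), onset_frame = integer(),
               duration_frames = integer(), magnitude = numeric())
  list(stack = out, log = log)
}

#' Generate tone-plus-noise test audio
#'
#' @param duration seconds.
#' @param fs sample rate, Hz (default 96 kHz, the recorder's rate).
#' @param tones list of `c(freq_hz, amplitude)` pairs; every frequency must
#'   be below the Nyquist frequency `fs/2`.
#' @param noise_sd white-noise sd (full-scale units).
#' @param seed RNG seed; fixed seed gives a bit-identical waveform.
#' @return numeric waveform in `[-1, 1]` with attribute `fs`.
#' @export
generate_test_audio <- function(duration, fs = 96000, tones = list(),
                                noise_sd = 0, seed = 1L) {
  stopifnot_scalar(duration, "duration", positive = TRUE)
  stopifnot_scalar(fs, "fs", positive = TRUE)
  for (tn in tones) {
    if (tn[1] >= fs / 2)
      stop(sprintf("tone at %g Hz is at/above Nyquist (%g Hz)", tn[1], fs / 2),
           call. = FALSE)
  }
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  for (tn in tones) x <- x + tn[2] * sin(2 * pi * tn[1] * t)
  if (noise_sd > 0) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    x <- x + stats::rnorm(n, sd = noise_sd)
  }
  attr(x, "fs") <- fs
  x
}

#' Generate synthetic descent footage with depth-dependent attenuation
#'
#' Emulates the camera's drop through the water column: per-frame mean color
#' starts blue-green near the surface and decays exponentially with depth
#' (blue fastest), leaving only red-LED backscatter at the bottom. Depth
#' grows linearly at `rate_m_s` from `drop_frame` onward.
#'
#' @param bottom_depth m.
#' @param rate_m_s descent rate (default 1.84).
#' @param fps frames per second.
#' @param width,height frame size (small frames suffice: only channel means
#'   are analysed).
#' @param pre_roll_s seconds of surface footage before the drop.
#' @param decay_g,decay_b e-folding depths (m) of green and blue.
#' @param surface_rgb channel intensities at 0 m.
#' @param bottom_red red intensity reached at depth.
#' @param noise_sd additive noise sd.
#' @param seed RNG seed.
#' @return list with `stack` (a `frame_stack`), `drop_frame` (1-based index
#'   of the first descending frame) and the generator parameters.
#' @export
generate_descent <- function(bottom_depth = 260, rate_m_s = 1.84, fps = 30,
                             width = 32, height = 24, pre_roll_s = 2,
                             decay_g = 18, decay_b = 12,
                             surface_rgb = c(60, 140, 180), bottom_red = 40,
                             noise_sd = 1, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  n_pre <- round(pre_roll_s * fps)
  n_desc <- ceiling(bottom_depth / rate_m_s * fps)
  drop_frame <- n_pre + 1L
  n <- n_pre + n_desc
  frames <- vector("list", n)
  for (k in seq_len(n)) {
    depth <- max(0, (k - drop_frame) / fps * rate_m_s)
    r <- surface_rgb[1] + (bottom_red - surface_rgb[1]) * (1 - exp(-depth / 40))
    g <- surface_rgb[2] * exp(-depth / decay_g)
    b <- surface_rgb[3] * exp(-depth / decay_b)
    img <- array(rep(c(r, g, b), each = height * width), c(height, width, 3))
    if (noise_sd > 0)
      img <- img + array(stats::rnorm(length(img), sd = noise_sd), dim(img))
    frames[[k]] <- round(pmin(pmax(img, 0), 255))
  }
  stack <- frame_stack(frames, fps = fps,
                       start_time = as.POSIXct("2025-08-03 12:00:00", tz = "UTC"),
                       segment_id = "descent")
  list(stack = stack, drop_frame = drop_frame, rate_m_s = rate_m_s,
       bottom_depth = bottom_depth, decay_g = decay_g, decay_b = decay_b)
}

#' Simulate the acoustic-release sensor log
#'
#' One row per minute: depth follows the bottom depth plus the tide, with
#' constant temperature and tilt and a noisy background-noise channel, as a
#' stand-in for the release's internal telemetry.
#'
#' @param tide a `tide_series`.
#' @param bottom_depth m (default 260).
#' @param temperature_c,tilt_deg,noise_mv constant sensor values.
#' @param seed RNG seed for the noise channel jitter.
#' @return data.frame `time`, `depth_m`, `temperature_c`, `tilt_deg`, `noise_mv`.
#' @export
generate_sensor_log <- function(tide, bottom_depth = 260, temperature_c = -0.18,
                                tilt_deg = 3.6, noise_mv = 169, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  data.frame(time = tide$time,
             depth_m = bottom_depth + tide$level,
             temperature_c = temperature_c,
             tilt_deg = tilt_deg,
             noise_mv = noise_mv + stats::rnorm(nrow(tide), sd = 4))
}
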