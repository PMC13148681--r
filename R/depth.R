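# Mapping descent footage to depth and extracting the RGB-versus-depth
# light-attenuation profile.

#' Mean descent rate from bottom depth and drop duration
#'
#' @param bottom_depth_m depth reached, m (> 0).
#' @param descent_duration_s time from release to touchdown, s (> 0).
#' @return rate in m/s. 260 m in 141 s (2 min 21 s) gives 1.84 m/s, i.e. a
#'   vertical resolution of rate/fps ~ 6 cm per frame at 30 fps.
#' @export
descent_rate <- function(bottom_depth_m, descent_duration_s) {
  stopifnot_scalar(bottom_depth_m, "bottom_depth_m", positive = TRUE)
  stopifnot_scalar(descent_duration_s, "descent_duration_s", positive = TRUE)
  bottom_depth_m / descent_duration_s
}

#' Depth of each frame of a descent stack
#'
#' Assumes a constant rate of descent from `drop_frame` onward:
#' `depth(k) = rate * (k - drop_frame) / fps`, clipped to
#' `[0, bottom_depth]`. Frames before the drop are at 0 m.
#'
#' @param stack a `frame_stack`.
#' @param drop_frame 1-based index of the first descending frame.
#' @param rate_m_s descent rate, m/s.
#' @param bottom_depth_m optional clip depth.
#' @return numeric vector of depths (m), one per frame.
#' @export
frames_to_depth <- function(stack, drop_frame, rate_m_s, bottom_depth_m = Inf) {
  n <- length(stack$frames)
  if (drop_frame < 1 || drop_frame > n)
    stop("'drop_frame' outside the stack", call. = FALSE)
  k <- seq_len(n)
  pmin(pmax(rate_m_s * (k - drop_frame) / stack$fps, 0), bottom_depth_m)
}

#' RGB-versus-depth attenuation profile
#'
#' Bins the per-frame mean channel intensities by depth and reports, per
#' bin, the mean R, G, B. Also reports the shallowest depth below which
#' both green and blue stay under `floor_intensity` — the depth where
#' conditions become indistinguishable from the red-lit seafloor.
#'
#' @param stack a `frame_stack` of the descent.
#' @param depths per-frame depths from [frames_to_depth()].
#' @param bin_m depth bin width, m (default 1).
#' @param floor_intensity intensity floor for the transition-depth report
#'   (default 10 of 255).
#' @return a `descent_profile`: list with `profile` (data.frame `depth_m`
#'   = bin centers, `mean_r`, `mean_g`, `mean_b`, `n_frames`; empty bins
#'   are absent), `transition_depth_m`, `bin_m`.
#' @export
rgb_depth_profile <- function(stack, depths, bin_m = 1, floor_intensity = 10) {
  if (length(depths) != length(stack$frames))
    stop("'depths' must have one value per frame", call. = FALSE)
  rgb <- t(vapply(stack$frames, mean_color, numeric(3)))
  bin <- floor(depths / bin_m)
  agg <- stats::aggregate(rgb, by = list(bin = bin), FUN = mean)
  cnt <- as.vector(table(factor(bin, levels = agg$bin)))
  prof <- data.frame(depth_m = (agg$bin + 0.5) * bin_m,
                     mean_r = agg$r, mean_g = agg$g, mean_b = agg$b,
                     n_frames = cnt)
  prof <- prof[order(prof$depth_m), ]
  below_floor <- prof$mean_g < floor_intensity & prof$mean_b < floor_intensity
  trans <- NA_real_
  if (any(below_floor)) {
    # shallowest depth from which G and B stay below the floor to the bottom
    stays <- rev(cumprod(rev(below_floor))) == 1
    if (any(stays)) trans <- min(prof$depth_m[stays])
  }
  structure(list(profile = prof, transition_depth_m = trans, bin_m = bin_m),
            class = "descent_profile")
}
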