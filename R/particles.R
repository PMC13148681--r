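# Particle quantification: background removal, binarization, counting,
# area-fraction integration, mean color, and transient-anomaly flagging.

# Reduce an RGB frame to the channel used for particle detection. Under
# red-LED illumination at the seafloor only red carries signal; during
# descent, luminance.
to_gray <- function(frame, channel = c("red", "luminance")) {
  channel <- match.arg(channel)
  if (channel == "red") frame[, , 1]
  else 0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
}

#' Estimate the static background of a segment
#'
#' Per-pixel temporal median over a window of frames. Static or slowly
#' varying features (the mooring line, the reflective recorder end-cap,
#' sediment stuck to the lens) survive into the background; particles in
#' motion do not, because each pixel sees a particle for only a small
#' minority of frames. The first frame is excluded (its power-on brightness
#' spike is an instrument artifact).
#'
#' @param stack a `frame_stack`.
#' @param window number of frames to use (>= 3); windows longer than the
#'   stack are clipped with a warning.
#' @param channel detection channel, `"red"` (seafloor) or `"luminance"`.
#' @param exclude_first drop frame 1 from the estimate (default TRUE).
#' @return a `background_model`: list with `background` (H x W matrix),
#'   `method`, `window`, `channel`.
#' @export
estimate_background <- function(stack, window = 30L,
                                channel = c("red", "luminance"),
                                exclude_first = TRUE) {
  channel <- match.arg(channel)
  n <- length(stack$frames)
  idx <- seq_len(n)
  if (exclude_first && n > 3L) idx <- idx[-1L]
  if (window < 3L) stop("'window' must be >= 3 frames", call. = FALSE)
  if (window > length(idx)) {
    warning(sprintf("window (%d) exceeds usable stack length (%d); clipped",
                    window, length(idx)))
    window <- length(idx)
  }
  idx <- idx[seq_len(window)]
  h <- dim(stack$frames[[1]])[1]; w <- dim(stack$frames[[1]])[2]
  m <- matrix(0, h * w, length(idx))
  for (j in seq_along(idx)) m[, j] <- as.vector(to_gray(stack$frames[[idx[j]]], channel))
  bg <- matrix(matrixStats::rowMedians(m), h, w)
  structure(list(background = bg, method = "temporal_median",
                 window = window, channel = channel),
            class = "background_model")
}

# 8-connected component labelling: EBImage::bwlabel gives 4-connected
# labels; labels touching diagonally are merged with a union-find pass so
# components follow the 8-neighborhood convention.
label_components8 <- function(bw) {
  labm <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw * 1)))
  nlab <- max(labm)
  if (nlab <= 1L) return(labm)
  h <- nrow(labm); w <- ncol(labm)
  a1 <- labm[-h, -w]; b1 <- labm[-1, -1]   # down-right diagonal
  a2 <- labm[-1, -w]; b2 <- labm[-h, -1]   # up-right diagonal
  sel1 <- a1 > 0 & b1 > 0 & a1 != b1
  sel2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
  if (nrow(pairs) == 0L) return(labm)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  remap <- match(root, sort(unique(root)))
  labm[labm > 0] <- remap[labm[labm > 0]]
  labm
}

# Otsu threshold on the residual, with a floor to avoid splitting a
# noise-only histogram into "particles". Residuals are 0-255.
residual_threshold <- function(residual, policy, floor_value = 10, fixed = 50) {
  if (identical(policy, "fixed")) return(fixed)
  rng <- range(residual)
  if (rng[2] - rng[1] < 1e-9) return(floor_value)
  th <- EBImage::otsu(EBImage::Image(residual / 255), range = c(0, 1)) * 255
  max(th, floor_value)
}

#' Quantify particles in one frame
#'
#' Subtracts the background from the detection channel, clips at zero,
#' binarizes the residual (Otsu threshold with a noise floor, or a fixed
#' threshold), and labels 8-connected components. Components of at least
#' `min_blob_px` pixels are particles: the count is the number of
#' components and the area fraction A is total component pixels divided by
#' the image size (A / (width x height)). Mean RGB is computed on the
#' original frame, not the residual.
#'
#' @param frame `H x W x 3` array, intensities 0--255.
#' @param background a `background_model` with matching shape.
#' @param threshold_policy `"otsu"` (default) or `"fixed"`.
#' @param min_blob_px minimum component size in px (default 2; single-pixel
#'   noise rejected).
#' @param fixed_threshold residual threshold used when
#'   `threshold_policy = "fixed"`.
#' @param floor_threshold lower bound on the Otsu threshold (default 10).
#' @return one-row data.frame: `area_fraction`, `count`, `mean_r`, `mean_g`,
#'   `mean_b`, `max_blob_px`, `max_blob_x`, `max_blob_y`, `saturated`.
#' @export
quantify_frame <- function(frame, background, threshold_policy = c("otsu", "fixed"),
                           min_blob_px = 2L, fixed_threshold = 50,
                           floor_threshold = 10) {
  threshold_policy <- match.arg(threshold_policy)
  gray <- to_gray(frame, background$channel)
  if (!identical(dim(gray), dim(background$background)))
    stop("frame and background shapes differ", call. = FALSE)
  residual <- pmax(gray - background$background, 0)
  th <- residual_threshold(residual, threshold_policy,
                           floor_value = floor_threshold, fixed = fixed_threshold)
  bw <- residual > th
  saturated <- mean(gray >= 254) > 0.99
  count <- 0L; area <- 0L
  max_blob <- c(px = 0, x = NA_real_, y = NA_real_)
  if (any(bw)) {
    labm <- label_components8(bw)
    sizes <- tabulate(labm[labm > 0])
    keep <- which(sizes >= min_blob_px)
    count <- length(keep)
    area <- sum(sizes[keep])
    if (count > 0L) {
      big <- keep[which.max(sizes[keep])]
      # labm keeps the matrix layout: dim1 = rows (y), dim2 = cols (x)
      idx <- which(labm == big, arr.ind = TRUE)
      max_blob <- c(px = sizes[big], x = mean(idx[, 2]), y = mean(idx[, 1]))
    }
  }
  mrgb <- mean_color(frame)
  data.frame(area_fraction = area / length(gray), count = count,
             mean_r = mrgb[1], mean_g = mrgb[2], mean_b = mrgb[3],
             max_blob_px = max_blob[["px"]], max_blob_x = max_blob[["x"]],
             max_blob_y = max_blob[["y"]], saturated = saturated)
}

#' Mean color intensity of a frame
#' @param frame `H x W x 3` array.
#' @return named numeric triplet (r, g, b), each the arithmetic mean of one
#'   channel over all pixels, in `[0, 255]`.
#' @export
mean_color <- function(frame) {
  if (length(dim(frame)) != 3L || dim(frame)[3] != 3L)
    stop("'frame' must be a 3-channel array", call. = FALSE)
  c(r = mean(frame[, , 1]), g = mean(frame[, , 2]), b = mean(frame[, , 3]))
}

#' Quantify every frame of a segment
#'
#' Estimates the background from the segment itself (no carry-over between
#' segments: they are separated by recording pauses) and applies
#' [quantify_frame()] to each frame.
#'
#' @inheritParams quantify_frame
#' @param stack a `frame_stack`.
#' @param background_window frames used for the temporal median.
#' @param channel detection channel.
#' @return data.frame with one row per frame: `segment_id`, `frame`,
#'   `time`, and the [quantify_frame()] columns.
#' @export
quantify_segment <- function(stack, background_window = 30L,
                             channel = c("red", "luminance"),
                             threshold_policy = c("otsu", "fixed"),
                             min_blob_px = 2L, fixed_threshold = 50,
                             floor_threshold = 10) {
  channel <- match.arg(channel); threshold_policy <- match.arg(threshold_policy)
  bg <- estimate_background(stack, window = background_window, channel = channel)
  times <- frame_times(stack)
  res <- lapply(seq_along(stack$frames), function(k)
    quantify_frame(stack$frames[[k]], bg, threshold_policy = threshold_policy,
                   min_blob_px = min_blob_px, fixed_threshold = fixed_threshold,
                   floor_threshold = floor_threshold))
  out <- do.call(rbind, res)
  cbind(data.frame(segment_id = stack$segment_id,
                   frame = seq_along(stack$frames), time = times), out)
}

#' Flag transient anomalies in a per-frame statistics series
#'
#' Three flags, matching the anomaly types seen in fixed-camera footage:
#' `FIRST_FRAME` if the first frame's mean detection-channel intensity
#' exceeds the segment median by `spike_sigma` robust (MAD) deviations;
#' `ATTACHMENT` if the area fraction jumps and stays elevated for at least
#' `glow_window` frames while the largest component's centroid stays nearly
#' static; `GLOW` if mean red rises (near-)monotonically over at least
#' `glow_window` frames without a matching rise in particle count.
#'
#' @param stats data.frame from [quantify_segment()] (time-ordered).
#' @param spike_sigma robust deviations for the first-frame test (default 5).
#' @param glow_window minimum persistence in frames (default 10).
#' @param jump_factor area elevation factor over the series median that
#'   counts as a jump (default 2).
#' @param centroid_tol_px maximum centroid drift (px) still called static.
#' @return `stats` with an added character column `flags`
#'   (comma-separated flags, `""` if none).
#' @export
flag_anomalies <- function(stats, spike_sigma = 5, glow_window = 10L,
                           jump_factor = 2, centroid_tol_px = 3) {
  n <- nrow(stats)
  flags <- rep("", n)
  add_flag <- function(i, f) flags[i] <<- ifelse(flags[i] == "", f, paste(flags[i], f, sep = ","))
  mr <- stats$mean_r
  med <- stats::median(mr[-1]); s <- stats::mad(mr[-1])
  if (n >= 2 && is.finite(s) && mr[1] > med + spike_sigma * max(s, 0.5))
    add_flag(1L, "FIRST_FRAME")
  if (n >= glow_window) {
    a <- stats$area_fraction
    base <- stats::median(a)
    elevated <- a > jump_factor * max(base, 1e-6)
    r <- rle(elevated)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= glow_window)) {
      idx <- starts[j]:ends[j]
      cx <- stats$max_blob_x[idx]; cy <- stats$max_blob_y[idx]
      drift <- sqrt(stats::var(cx, na.rm = TRUE) + stats::var(cy, na.rm = TRUE))
      if (is.finite(drift) && drift <= centroid_tol_px) add_flag(idx, "ATTACHMENT")
    }
    # GLOW: sustained quasi-monotone red rise with no count rise
    dr <- diff(mr)
    rising <- dr > 0
    r2 <- rle(rising)
    ends2 <- cumsum(r2$lengths); starts2 <- ends2 - r2$lengths + 1L
    for (j in which(r2$values & r2$lengths >= glow_window - 1L)) {
      idx <- starts2[j]:(ends2[j] + 1L)
      cnt <- stats$count[idx]
      rise_r <- mr[idx[length(idx)]] - mr[idx[1]]
      cnt_trend <- stats::median(cnt[(length(cnt) %/% 2 + 1):length(cnt)]) -
        stats::median(cnt[1:(length(cnt) %/% 2)])
      if (rise_r > 2 && cnt_trend <= max(2, 0.1 * stats::median(cnt)))
        add_flag(idx, "GLOW")
    }
  }
  stats$flags <- flags
  stats
}

#' Sliding-median smoothing of a segment-cadence series
#'
#' Centered median filter expressed in physical units: a 3-h window at the
#' 20-min segment cadence is a 9-sample kernel. Edges use shrinking
#' windows; missing values are dropped within each window.
#'
#' @param x numeric vector, one value per recorded segment.
#' @param window_h window length in hours.
#' @param cadence_min sample spacing in minutes (default 20).
#' @return smoothed vector.
#' @export
sliding_median <- function(x, window_h = 3, cadence_min = 20) {
  if (window_h * 60 < cadence_min) {
    warning("window shorter than the cadence; returning the series unchanged")
    return(x)
  }
  k <- round(window_h * 60 / cadence_min)
  centered_median(x, k)
}
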