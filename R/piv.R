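# Digital particle image velocimetry (DPIV): FFT cross-correlation per
# interrogation window, 3-point Gaussian subpixel peak fit, optional
# multi-pass window refinement, normalized-median vector validation, and
# reduction of vector fields to one dominant flow per video segment.
#
# Image convention: matrices are row = y (down), col = x (right).
# Displacements (u, v) are px/frame with u = +x (right) and v = +y (DOWN,
# image convention). Directions reported by dominant_flow() flip the y axis
# (CCW from +x, y up), the convention used for flow headings.

# Correlate two zero-mean windows; returns the correlation surface with the
# zero-displacement term at [1, 1] and circular wrap-around.
xcorr_fft <- function(a, b) {
  fa <- stats::fft(a); fb <- stats::fft(b)
  Re(stats::fft(Conj(fa) * fb, inverse = TRUE)) / length(a)
}

# 3-point Gaussian subpixel refinement along one axis; parabolic fallback
# when a neighbor is non-positive (log undefined).
subpixel_offset <- function(cm, c0, cp) {
  if (cm > 0 && c0 > 0 && cp > 0) {
    den <- 2 * (log(cm) + log(cp) - 2 * log(c0))
    if (abs(den) > 1e-12) return((log(cm) - log(cp)) / den)
  }
  den <- 2 * (cm + cp - 2 * c0)
  if (abs(den) > 1e-12) (cm - cp) / den else 0
}

# Displacement of window b relative to window a (integer + subpixel),
# plus the correlation peak ratio. Returns c(u, v, ratio, r) or NULL if the
# window carries no signal (near-zero variance or a peak correlation
# coefficient too weak to be particle pattern match).
window_displacement <- function(a, b, min_corr = 0.25) {
  va <- stats::var(as.vector(a)); vb <- stats::var(as.vector(b))
  if (!is.finite(va) || !is.finite(vb) || va < 1e-10 || vb < 1e-10) return(NULL)
  a0 <- a - mean(a); b0 <- b - mean(b)
  cc <- xcorr_fft(a0, b0)
  r_peak <- max(cc) * length(a0) / sqrt(sum(a0^2) * sum(b0^2))
  if (!is.finite(r_peak) || r_peak < min_corr) return(NULL)
  w <- nrow(cc)
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  # wrap indices to signed displacements
  dv <- pk[1] - 1L; du <- pk[2] - 1L
  if (dv > w / 2) dv <- dv - w
  if (du > ncol(cc) / 2) du <- du - ncol(cc)
  wrap <- function(i, n) ((i - 1) %% n) + 1
  c0 <- cc[pk[1], pk[2]]
  cu_m <- cc[pk[1], wrap(pk[2] - 1, ncol(cc))]
  cu_p <- cc[pk[1], wrap(pk[2] + 1, ncol(cc))]
  cv_m <- cc[wrap(pk[1] - 1, w), pk[2]]
  cv_p <- cc[wrap(pk[1] + 1, w), pk[2]]
  u <- du + subpixel_offset(cu_m, c0, cu_p)
  v <- dv + subpixel_offset(cv_m, c0, cv_p)
  # peak ratio: highest peak vs second peak outside its 3x3 neighborhood
  cc2 <- cc
  ri <- wrap(pk[1] + (-1:1), w); ci <- wrap(pk[2] + (-1:1), ncol(cc))
  cc2[ri, ci] <- -Inf
  second <- max(cc2)
  ratio <- if (is.finite(second) && second > 0) c0 / second else Inf
  c(u = unname(u), v = unname(v), ratio = unname(ratio))
}

#' PIV displacement field between two frames
#'
#' Splits the frame pair into interrogation windows and estimates, per
#' window, the displacement as the argmax of the FFT-based cross-correlation
#' of the zero-mean windows, refined to subpixel precision by a 3-point
#' Gaussian fit in x and y. With `passes > 1`, the window is halved each
#' pass and the second frame's windows are offset by the previous pass's
#' (integer-rounded) local displacement before correlating, extending the
#' dynamic range.
#'
#' @param frame_a,frame_b background-removed grayscale matrices of equal
#'   shape (an RGB array is reduced via its red channel).
#' @param window_px interrogation window side in px (>= 16); must fit inside
#'   the image.
#' @param overlap_fraction window overlap (0 to < 1; default 0.5).
#' @param passes number of refinement passes (default 2: `window_px` then
#'   `window_px / 2`).
#' @return a `vector_field`: list with matrices `x`, `y` (window centers,
#'   px), `u`, `v` (displacement px/frame; +x right, +y down), `valid`,
#'   `peak_ratio`, and `window_px` of the final pass.
#' @export
piv_pair <- function(frame_a, frame_b, window_px = 64L, overlap_fraction = 0.5,
                     passes = 2L) {
  if (length(dim(frame_a)) == 3L) frame_a <- frame_a[, , 1]
  if (length(dim(frame_b)) == 3L) frame_b <- frame_b[, , 1]
  if (!identical(dim(frame_a), dim(frame_b)))
    stop("frames must have the same shape", call. = FALSE)
  if (window_px < 16L) stop("'window_px' must be >= 16", call. = FALSE)
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("'overlap_fraction' must be in [0, 1)", call. = FALSE)
  h <- nrow(frame_a); w <- ncol(frame_a)
  if (window_px > min(h, w))
    stop("interrogation window larger than the image", call. = FALSE)
  pred <- NULL
  field <- NULL
  wp <- as.integer(window_px)
  for (p in seq_len(passes)) {
    if (p > 1L && wp %/% 2L >= 16L) wp <- wp %/% 2L
    field <- piv_single_pass(frame_a, frame_b, wp, overlap_fraction, pred)
    pred <- field
  }
  field
}

piv_single_pass <- function(A, B, wp, overlap, pred) {
  h <- nrow(A); w <- ncol(A)
  step <- max(1L, as.integer(round(wp * (1 - overlap))))
  r0s <- seq(1L, h - wp + 1L, by = step)
  c0s <- seq(1L, w - wp + 1L, by = step)
  ny <- length(r0s); nx <- length(c0s)
  u <- v <- ratio <- matrix(NA_real_, ny, nx)
  valid <- matrix(FALSE, ny, nx)
  xs <- c0s + (wp - 1) / 2; ys <- r0s + (wp - 1) / 2
  win_b <- function(r0, c0, dv, du) {
    rb <- (r0 + dv):(r0 + dv + wp - 1L)
    cb <- (c0 + du):(c0 + du + wp - 1L)
    if (min(rb) < 1L || max(rb) > h || min(cb) < 1L || max(cb) > w) NULL
    else B[rb, cb]
  }
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    r0 <- r0s[i]; c0 <- c0s[j]
    du0 <- 0L; dv0 <- 0L
    if (!is.null(pred)) {
      pi <- which.min(abs(pred$y[, 1] - ys[i]))
      pj <- which.min(abs(pred$x[1, ] - xs[j]))
      if (isTRUE(pred$valid[pi, pj])) {
        du0 <- as.integer(round(pred$u[pi, pj]))
        dv0 <- as.integer(round(pred$v[pi, pj]))
      }
    }
    a <- A[r0:(r0 + wp - 1L), c0:(c0 + wp - 1L)]
    if (is.null(win_b(r0, c0, dv0, du0))) { du0 <- 0L; dv0 <- 0L }
    # discrete window offset, iterated: correlate, shift the second window
    # by the accumulated integer displacement, and repeat until the
    # residual integer part is zero — there the 3-point fit is unbiased
    # (and exactly zero for pure integer shifts)
    est_u <- du0; est_v <- dv0
    d <- NULL
    for (it in 1:4) {
      # split the offset between the two windows so it stays in bounds
      # even near the frame edges (b forward by sb, a backward by est - sb)
      sv_b <- max(min(est_v, h - (r0 + wp - 1L)), 1L - r0)
      su_b <- max(min(est_u, w - (c0 + wp - 1L)), 1L - c0)
      sv_a <- est_v - sv_b; su_a <- est_u - su_b
      ra <- (r0 - sv_a):(r0 - sv_a + wp - 1L)
      ca <- (c0 - su_a):(c0 - su_a + wp - 1L)
      dd <- NULL
      if (min(ra) >= 1L && max(ra) <= h && min(ca) >= 1L && max(ca) <= w) {
        aw <- if (sv_a == 0L && su_a == 0L) a else A[ra, ca]
        dd <- window_displacement(aw, win_b(r0, c0, sv_b, su_b))
      }
      if (is.null(dd)) break
      d <- c(u = est_u - du0 + dd[["u"]], v = est_v - dv0 + dd[["v"]],
             ratio = dd[["ratio"]])
      if (round(dd[["u"]]) == 0 && round(dd[["v"]]) == 0) break
      est_u <- est_u + as.integer(round(dd[["u"]]))
      est_v <- est_v + as.integer(round(dd[["v"]]))
    }
    if (is.null(d)) next
    u[i, j] <- d[["u"]] + du0
    v[i, j] <- d[["v"]] + dv0
    ratio[i, j] <- d[["ratio"]]
    valid[i, j] <- TRUE
  }
  structure(list(x = matrix(xs, ny, nx, byrow = TRUE),
                 y = matrix(ys, ny, nx),
                 u = u, v = v, valid = valid, peak_ratio = ratio,
                 window_px = wp),
            class = "vector_field")
}

#' Normalized-median validation of a PIV vector field
#'
#' Flags spurious vectors by the normalized median test: each vector is
#' compared with the median of its (up to) 8 valid neighbors; the residual
#' is normalized by the median of the neighbors' own residuals plus `eps`.
#' Vectors whose combined (Euclidean over u, v) normalized residual exceeds
#' `residual_threshold` are marked invalid. No in-fill is performed.
#'
#' @param field a `vector_field`.
#' @param eps noise floor of the normalization, px (default 0.1).
#' @param residual_threshold invalidation threshold (default 2).
#' @return the field with its `valid` mask updated.
#' @export
validate_vectors <- function(field, eps = 0.1, residual_threshold = 2) {
  ny <- nrow(field$u); nx <- ncol(field$u)
  norm_res <- function(comp) {
    out <- matrix(0, ny, nx)
    for (i in seq_len(ny)) for (j in seq_len(nx)) {
      if (!field$valid[i, j]) next
      ri <- max(1, i - 1):min(ny, i + 1)
      ci <- max(1, j - 1):min(nx, j + 1)
      nb <- comp[ri, ci]
      ok <- field$valid[ri, ci]
      nb[which(ri == i), which(ci == j)] <- NA  # exclude the center vector
      nbrs <- nb[ok & !is.na(nb)]
      if (length(nbrs) < 3) next
      med <- stats::median(nbrs)
      fluct <- abs(nbrs - med)
      out[i, j] <- abs(comp[i, j] - med) / (stats::median(fluct) + eps)
    }
    out
  }
  ru <- norm_res(field$u); rv <- norm_res(field$v)
  bad <- sqrt(ru^2 + rv^2) > residual_threshold
  field$valid <- field$valid & !bad
  field
}

#' Dominant flow of a segment
#'
#' Reduces the vector fields of a segment's analysed frame pairs to one
#' flow: speed is the arithmetic mean of valid vector magnitudes scaled to
#' px/s, direction is the circular (resultant-vector) mean of vector
#' angles in degrees CCW from +x with y up. Circular averaging is
#' essential: angles of 350 and 10 degrees must average to 0, not 180.
#'
#' @param fields list of `vector_field` (or a single one).
#' @param fps frames per second of the source video.
#' @return one-row data.frame: `speed_px_s`, `direction_deg`,
#'   `n_vectors_used`, `missing` (TRUE when no valid vector exists — a
#'   missing flow, never a zero one).
#' @export
dominant_flow <- function(fields, fps) {
  if (inherits(fields, "vector_field")) fields <- list(fields)
  u <- unlist(lapply(fields, function(f) f$u[f$valid]))
  v <- unlist(lapply(fields, function(f) f$v[f$valid]))
  ok <- is.finite(u) & is.finite(v)
  u <- u[ok]; v <- v[ok]
  if (length(u) == 0L)
    return(data.frame(speed_px_s = NA_real_, direction_deg = NA_real_,
                      n_vectors_used = 0L, missing = TRUE))
  mag <- sqrt(u^2 + v^2)
  ang <- wrap360(rad2deg(atan2(-v, u)))  # flip rows: y up
  data.frame(speed_px_s = mean(mag) * fps,
             direction_deg = circular_mean(ang, w = mag),
             n_vectors_used = length(u), missing = FALSE)
}

#' PIV analysis of one video segment
#'
#' Convenience wrapper for the per-file flow estimate: removes the
#' background, forms consecutive pairs among the first `n_frames` frames
#' (9 pairs for the conventional 10-frame burst), runs [piv_pair()] and
#' [validate_vectors()] on each pair, and reduces to the segment's
#' [dominant_flow()].
#'
#' @param stack a `frame_stack`.
#' @param n_frames frames analysed from the segment start (default 10).
#' @param window_px,overlap_fraction,passes see [piv_pair()].
#' @param channel detection channel for the residuals.
#' @return one-row data.frame: `segment_id`, `time` (segment start),
#'   `speed_px_s`, `direction_deg`, `n_vectors_used`, `missing`.
#' @export
piv_segment <- function(stack, n_frames = 10L, window_px = 64L,
                        overlap_fraction = 0.5, passes = 2L,
                        channel = c("red", "luminance")) {
  channel <- match.arg(channel)
  n_frames <- min(n_frames, length(stack$frames))
  if (n_frames < 2L)
    stop("PIV needs at least two frames", call. = FALSE)
  sub <- subsample(stack, n_frames)
  bg <- estimate_background(sub, window = max(3L, n_frames - 1L),
                            channel = channel, exclude_first = n_frames > 4L)
  resid <- lapply(sub$frames, function(f) pmax(to_gray(f, channel) - bg$background, 0))
  fields <- vector("list", n_frames - 1L)
  for (k in seq_len(n_frames - 1L)) {
    fld <- piv_pair(resid[[k]], resid[[k + 1L]], window_px = window_px,
                    overlap_fraction = overlap_fraction, passes = passes)
    fields[[k]] <- validate_vectors(fld)
  }
  flow <- dominant_flow(fields, fps = stack$fps)
  cbind(data.frame(segment_id = stack$segment_id, time = stack$start_time), flow)
}
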