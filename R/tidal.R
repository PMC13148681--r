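# Relating the per-segment dominant flow to tidal forcing: alignment,
# circular-to-linear angle handling, Pearson correlation, periodograms.

#' Align a flow series with a sea-level rate series
#'
#' The tide gauge samples every minute, the flow once per 20-min segment;
#' the rate is linearly interpolated to each flow timestamp. Segments with
#' a missing flow estimate are dropped (never imputed).
#'
#' @param flow data.frame with `time`, `speed_px_s`, `direction_deg`,
#'   optionally `missing` (rows with `missing = TRUE` or NA speed are
#'   dropped).
#' @param rate data.frame with `time`, `rate` (m/h), e.g. from
#'   [sea_level_rate()].
#' @return data.frame pairing each retained flow row with the interpolated
#'   `rate`; attribute `n_pairs`.
#' @export
align_series <- function(flow, rate) {
  keep <- rep(TRUE, nrow(flow))
  if ("missing" %in% names(flow)) keep <- keep & !flow$missing
  if ("speed_px_s" %in% names(flow)) keep <- keep & is.finite(flow$speed_px_s)
  flow <- flow[keep, , drop = FALSE]
  if (nrow(flow) == 0L) stop("no usable flow samples", call. = FALSE)
  tf <- as.numeric(flow$time); tr <- as.numeric(rate$time)
  if (max(tf) < min(tr) || min(tf) > max(tr))
    stop("flow and rate series do not overlap in time", call. = FALSE)
  ri <- stats::approx(tr, rate$rate, xout = tf, rule = 1)$y
  out <- cbind(flow, rate = ri)
  out <- out[is.finite(out$rate), , drop = FALSE]
  attr(out, "n_pairs") <- nrow(out)
  out
}

#' Signed angle of a flow direction about a reference axis
#'
#' Linearizes the circular direction for correlation with a signed scalar
#' forcing: the wrapped difference `direction - flow_axis` mapped into
#' (-180, 180]. Flow along the axis gives 0, the reversed flow gives 180.
#'
#' @param direction_deg flow direction(s), degrees.
#' @param flow_axis_deg reference axis, degrees (e.g. from
#'   [estimate_flow_axis()]).
#' @return signed angle(s) in (-180, 180].
#' @export
signed_angle <- function(direction_deg, flow_axis_deg) {
  d <- (direction_deg - flow_axis_deg) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Estimate the dominant flow axis of a deployment
#'
#' The circular mean axis (directions pooled modulo 180, so ebb and flood
#' along one channel reinforce instead of cancelling).
#'
#' @param direction_deg vector of segment flow directions, degrees.
#' @return axis in `[0, 180)` degrees.
#' @export
estimate_flow_axis <- function(direction_deg) circular_axis(direction_deg)

#' Signed flow speed along an axis
#'
#' `speed * cos(direction - axis)`: positive when the flow has a component
#' along the axis, negative when reversed. An alternative linearization of
#' the circular direction that also carries the speed.
#'
#' @param speed speeds (px/s).
#' @param direction_deg directions (degrees).
#' @param flow_axis_deg reference axis (degrees).
#' @return signed speeds.
#' @export
signed_speed <- function(speed, direction_deg, flow_axis_deg) {
  speed * cos(deg2rad(direction_deg - flow_axis_deg))
}

#' Pearson correlation with its two-sided p-value
#'
#' @param x,y numeric vectors of equal length (n >= 3, finite values;
#'   non-finite pairs are dropped).
#' @param tag optional label of the variable pair.
#' @return a `correlation_result`: list with `r`, `p_value`, `n`,
#'   `variables`, and `defined` (FALSE when either input has zero
#'   variance, in which case `r` is NA).
#' @export
pearson_cor <- function(x, y, tag = "x~y") {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 finite pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(list(r = NA_real_, p_value = NA_real_, n = length(x),
                          variables = tag, defined = FALSE),
                     class = "correlation_result"))
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
                 variables = tag, defined = TRUE),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r(%s) = %.3f, p = %.3g, n = %d\n",
              x$variables, x$r, x$p_value, x$n))
  invisible(x)
}

#' Raw periodogram with chi-squared 95% confidence bounds
#'
#' Untapered, non-smoothed periodogram of a uniformly sampled series (the
#' mean is removed). Each ordinate of a raw periodogram is distributed as
#' power times chi-squared(2)/2, giving per-ordinate 95% bounds
#' `2 * power / qchisq(c(.975, .025), 2)`. Frequencies are reported per
#' hour.
#'
#' @param x numeric series at uniform cadence (no gaps; restrict to a
#'   contiguous span or pre-fill upstream).
#' @param cadence_min sample spacing in minutes.
#' @return data.frame `frequency_per_h`, `power`, `lo95`, `hi95`.
#' @export
periodogram_psd <- function(x, cadence_min) {
  if (length(x) < 4L) stop("series too short for a periodogram", call. = FALSE)
  if (any(!is.finite(x))) stop("series must be gap-free and finite", call. = FALSE)
  sp <- stats::spec.pgram(stats::ts(x, frequency = 1), taper = 0, detrend = TRUE,
                          demean = TRUE, plot = FALSE)
  # cycles/sample -> cycles/hour
  f_h <- sp$freq * 60 / cadence_min
  # raw periodogram ordinates ~ P * chisq(2)/2
  lo <- 2 * sp$spec / stats::qchisq(0.975, df = 2)
  hi <- 2 * sp$spec / stats::qchisq(0.025, df = 2)
  data.frame(frequency_per_h = f_h, power = sp$spec, lo95 = lo, hi95 = hi)
}
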