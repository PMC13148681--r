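# Internal helpers shared across modules.

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' Wrap angles into [0, 360)
#' @param deg numeric vector of angles in degrees.
#' @return angles reduced modulo 360 into `[0, 360)`.
#' @keywords internal
wrap360 <- function(deg) {
  w <- deg %% 360
  w[w > 360 - 1e-9] <- 0  # guard the floating-point edge of the modulus
  w
}

#' Circular mean of angles
#'
#' Resultant-vector mean direction. Angles 180 degrees apart do not cancel
#' into a meaningless arithmetic average; e.g. 350 and 10 average to 0.
#'
#' @param deg angles in degrees.
#' @param w optional non-negative weights (e.g. vector magnitudes).
#' @return mean direction in degrees in `[0, 360)`, or `NA` if the resultant
#'   vector has zero length.
#' @export
circular_mean <- function(deg, w = NULL) {
  deg <- deg[is.finite(deg)]
  if (length(deg) == 0L) return(NA_real_)
  if (is.null(w)) w <- rep(1, length(deg))
  th <- deg2rad(deg)
  s <- sum(w * sin(th)); c <- sum(w * cos(th))
  if (sqrt(s^2 + c^2) < 1e-12) return(NA_real_)
  wrap360(rad2deg(atan2(s, c)))
}

# Circular mean axis (undirected, mod 180): mean of doubled angles halved.
circular_axis <- function(deg) {
  deg <- deg[is.finite(deg)]
  if (length(deg) == 0L) return(NA_real_)
  th <- deg2rad(2 * deg)
  a <- rad2deg(atan2(mean(sin(th)), mean(cos(th)))) / 2
  a %% 180
}

#' NA-tolerant centered sliding median
#'
#' Centered running median with shrinking windows at the series edges.
#' Unlike [stats::runmed()] it tolerates missing values (dropped within each
#' window), which arise when recording segments fail or are skipped.
#'
#' @param x numeric vector (uniformly sampled).
#' @param k window length in samples; even values are rounded up to odd.
#' @return smoothed vector, same length as `x`.
#' @export
centered_median <- function(x, k) {
  n <- length(x)
  if (k <= 1L || n == 0L) return(x)
  if (k %% 2L == 0L) k <- k + 1L
  h <- (k - 1L) %/% 2L
  out <- vapply(seq_len(n), function(i) {
    w <- x[max(1L, i - h):min(n, i + h)]
    w <- w[is.finite(w)]
    if (length(w) == 0L) NA_real_ else stats::median(w)
  }, numeric(1))
  out
}

# Validate a scalar argument.
stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

# POSIXct in UTC from various inputs.
as_utc <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(as.numeric(x), origin = "1970-01-01", tz = "UTC"))
  as.POSIXct(x, tz = "UTC")
}

fmt_utc <- function(t) format(as_utc(t), "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
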