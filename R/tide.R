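#' Simulate a semidiurnal tide with a spring--neap envelope
#'
#' Sea level is modelled as a single principal lunar semidiurnal (M2)
#' constituent, level(t) = mean + A(t) sin(2 pi t / T), with T = 12.42 h,
#' whose amplitude A(t) is modulated by a sinusoidal fortnightly
#' (14.8-day) envelope: A(t) = amp * (1 - mod/2 + (mod/2) sin(2 pi t / T_sn)).
#' With `spring_neap_mod = 0` the amplitude is constant and the peak-to-trough
#' range equals `2 * semidiurnal_amp`. Optional white observation noise can be
#' added; the series is deterministic for a fixed seed.
#'
#' @param duration total span in seconds (at least two tidal cycles).
#' @param mean_level mean sea level in m (levels are reported relative to the
#'   gauge datum; use 0 for anomalies).
#' @param semidiurnal_amp M2 amplitude in m (half the tidal range).
#' @param spring_neap_mod fraction in `[0, 1]`: 0 = no fortnightly modulation,
#'   1 = amplitude swings between 0 and `semidiurnal_amp`.
#' @param sample_interval sampling interval in seconds (gauge cadence;
#'   default 60 s, one sample per minute).
#' @param noise_sd standard deviation of additive white noise in m (default 0).
#' @param seed integer RNG seed used only when `noise_sd > 0`.
#' @param start_time POSIXct start of the series (UTC).
#' @return a `tide_series`: data.frame with columns `time` (POSIXct UTC) and
#'   `level` (m), plus attributes `interval_s`.
#' @export
generate_tide <- function(duration, mean_level = 0, semidiurnal_amp = 1.5,
                          spring_neap_mod = 0, sample_interval = 60,
                          noise_sd = 0, seed = 1L,
                          start_time = as.POSIXct("2025-08-03 00:00:00", tz = "UTC")) {
  stopifnot_scalar(duration, "duration", positive = TRUE)
  stopifnot_scalar(sample_interval, "sample_interval")
  if (sample_interval <= 0) stop("'sample_interval' must be > 0", call. = FALSE)
  if (semidiurnal_amp < 0) stop("'semidiurnal_amp' must be >= 0", call. = FALSE)
  if (spring_neap_mod < 0 || spring_neap_mod > 1)
    stop("'spring_neap_mod' must be in [0, 1]", call. = FALSE)
  t_m2 <- 12.42 * 3600           # M2 period, s
  if (duration < 2 * t_m2)
    stop("'duration' must span at least two tidal cycles (2 x 12.42 h)", call. = FALSE)
  t_sn <- 14.8 * 86400           # spring-neap envelope period, s
  t <- seq(0, duration, by = sample_interval)
  amp_t <- semidiurnal_amp *
    (1 - spring_neap_mod / 2 + (spring_neap_mod / 2) * sin(2 * pi * t / t_sn))
  level <- mean_level + amp_t * sin(2 * pi * t / t_m2)
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    level <- level + stats::rnorm(length(level), sd = noise_sd)
  }
  out <- data.frame(time = as_utc(start_time) + t, level = level)
  attr(out, "interval_s") <- sample_interval
  class(out) <- c("tide_series", "data.frame")
  out
}

# Preserve caller RNG state across seeded simulation.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Rate of change of sea level
#'
#' Central finite difference of the level series (m/h), followed by a
#' centered sliding median (default 2 h window) to suppress gauge noise
#' before comparison with near-bed flow.
#'
#' @param tide a `tide_series` (or data.frame with `time`, `level`) at uniform
#'   sampling.
#' @param smooth_window_h median-filter window in hours; 0 disables smoothing.
#' @return data.frame with `time` and `rate` (m/h).
#' @export
sea_level_rate <- function(tide, smooth_window_h = 2) {
  if (nrow(tide) < 3) stop("need at least 3 samples to differentiate", call. = FALSE)
  t <- as.numeric(tide$time)
  dt <- diff(t)
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt))
    stop("tide series must be uniformly sampled", call. = FALSE)
  h <- dt[1]
  lv <- tide$level
  n <- length(lv)
  rate <- numeric(n)
  rate[2:(n - 1)] <- (lv[3:n] - lv[1:(n - 2)]) / (2 * h)
  rate[1] <- (lv[2] - lv[1]) / h
  rate[n] <- (lv[n] - lv[n - 1]) / h
  rate <- rate * 3600  # m/s -> m/h
  if (smooth_window_h > 0) {
    k <- max(1L, round(smooth_window_h * 3600 / h))
    rate <- centered_median(rate, k)
  }
  data.frame(time = tide$time, rate = rate)
}
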