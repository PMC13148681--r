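# End-to-end orchestration: simulate a synthetic deployment bundle to disk,
# and analyze a bundle through every stage with per-stage logging.

log_line <- function(stage, msg) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%OS1"), stage, msg))
}

#' Default pipeline configuration
#'
#' @param output_dir where bundles/results are written.
#' @param seed master RNG seed.
#' @param deployment_h simulated deployment span in hours.
#' @param scene a [scene_config()] (its `seed` is overridden by `seed`).
#' @param tide_amp_m,spring_neap_mod tide generator settings.
#' @param subsample_n frames analysed per segment.
#' @param piv_window_px,piv_passes PIV settings.
#' @param smooth_rate_h,smooth_features_h median windows for the sea-level
#'   rate (2 h) and for feature display series (3 h).
#' @param spectrogram settings list: `fft_size`, `time_resolution_s`, `band`.
#' @return named list.
#' @export
pipeline_config <- function(output_dir = tempfile("benthocam_"), seed = 1L,
                            deployment_h = 72,
                            scene = scene_config(width = 96, height = 72,
                                                 particle_density = 30,
                                                 frames_per_segment = 10),
                            tide_amp_m = 1.5, spring_neap_mod = 0.3,
                            subsample_n = 10L,
                            piv_window_px = 32L, piv_passes = 1L,
                            smooth_rate_h = 2, smooth_features_h = 3,
                            spectrogram = list(fft_size = 1024L,
                                               time_resolution_s = 10,
                                               band = c(20, 43000))) {
  scene$seed <- as.integer(seed)
  list(output_dir = output_dir, seed = as.integer(seed),
       deployment_h = deployment_h, scene = scene,
       tide_amp_m = tide_amp_m, spring_neap_mod = spring_neap_mod,
       subsample_n = subsample_n, piv_window_px = piv_window_px,
       piv_passes = piv_passes, smooth_rate_h = smooth_rate_h,
       smooth_features_h = smooth_features_h, spectrogram = spectrogram)
}

#' Simulate a full synthetic deployment bundle to disk
#'
#' Writes tide CSV, sensor-log CSV, duty-cycled scene segments (PNG
#' directories with JSON sidecars), ground-truth CSV, a short test WAV, the
#' recording schedule, and a manifest JSON with MD5 checksums of every
#' artifact. Deterministic: repeating a seed reproduces every checksum.
#'
#' @param config from [pipeline_config()].
#' @param force overwrite an existing non-empty output directory.
#' @return path of the bundle directory, invisibly; the manifest is at
#'   `manifest.json`.
#' @export
run_simulate <- function(config, force = FALSE) {
  out <- config$output_dir
  if (dir.exists(out) && length(dir(out)) > 0L && !force)
    stop(sprintf("output dir '%s' is non-empty; use force = TRUE", out), call. = FALSE)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_line("simulate", sprintf("seed %d, %g h deployment", config$seed, config$deployment_h))
  tide <- generate_tide(duration = config$deployment_h * 3600,
                        semidiurnal_amp = config$tide_amp_m,
                        spring_neap_mod = config$spring_neap_mod,
                        seed = config$seed)
  utils::write.csv(data.frame(timestamp = fmt_utc(tide$time), level_m = tide$level),
                   file.path(out, "tide.csv"), row.names = FALSE)
  sensor <- generate_sensor_log(tide, seed = config$seed)
  utils::write.csv(data.frame(timestamp = fmt_utc(sensor$time),
                              depth_m = sensor$depth_m,
                              temperature_c = sensor$temperature_c,
                              tilt_deg = sensor$tilt_deg,
                              noise_mv = sensor$noise_mv),
                   file.path(out, "sensor_log.csv"), row.names = FALSE)
  schedule <- generate_schedule(min(tide$time), total_h = config$deployment_h)
  scene <- generate_scene(config$scene, tide, schedule)
  seg_dir <- file.path(out, "segments")
  for (s in scene$segments)
    write_segment(s, file.path(seg_dir, s$segment_id), overwrite = force)
  utils::write.csv(data.frame(segment_id = schedule$segment_id,
                              start = fmt_utc(schedule$start),
                              duration_s = schedule$duration_s),
                   file.path(out, "schedule.csv"), row.names = FALSE)
  tr <- scene$truth$frames
  utils::write.csv(data.frame(segment = tr$segment, frame = tr$frame,
                              time = fmt_utc(tr$time), count = tr$count,
                              u = tr$u, v = tr$v, area_px = tr$area_px),
                   file.path(out, "truth.csv"), row.names = FALSE)
  jsonlite::write_json(list(anomalies = scene$truth$anomalies),
                       file.path(out, "truth_anomalies.json"), auto_unbox = TRUE)
  audio <- generate_test_audio(duration = 30, fs = 96000,
                               tones = list(c(1000, 0.3), c(30000, 0.1)),
                               noise_sd = 0.02, seed = config$seed)
  write_wav(audio, file.path(out, "audio.wav"))
  files <- dir(out, recursive = TRUE, full.names = TRUE)
  manifest <- data.frame(path = sub(paste0("^", out, "/?"), "", files),
                         md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(list(seed = config$seed, artifacts = manifest),
                       file.path(out, "manifest.json"), auto_unbox = TRUE)
  log_line("simulate", sprintf("%d segments written to %s", length(scene$segments), out))
  invisible(out)
}

#' Analyze a deployment bundle end to end
#'
#' Runs particle quantification, PIV dominant-flow estimation, tidal
#' correlation, periodograms, and the long-term spectrogram over a bundle
#' laid out as written by [run_simulate()] (or equivalently organized real
#' data). A failing segment is skipped with a logged reason, never aborting
#' the run. All results are written as CSV/JSON under
#' `<bundle>/results/`.
#'
#' @param config from [pipeline_config()]; `config$output_dir` is the
#'   bundle directory.
#' @return list with `stats` (per-frame particle stats), `flow`
#'   (per-segment dominant flow), `correlations`, `psd`, `spectrogram`,
#'   `n_segments_analyzed`, `results_dir`.
#' @export
run_analyze <- function(config) {
  bundle <- config$output_dir
  seg_dirs <- sort(dir(file.path(bundle, "segments"), full.names = TRUE))
  if (length(seg_dirs) == 0L) stop("no readable segments in bundle", call. = FALSE)
  res_dir <- file.path(bundle, "results")
  dir.create(res_dir, showWarnings = FALSE)
  stats_list <- list(); flow_list <- list(); skipped <- 0L
  for (sd in seg_dirs) {
    r <- tryCatch({
      stack <- load_segment(sd)
      sub <- subsample(stack, min(config$subsample_n, length(stack)))
      st <- quantify_segment(sub, background_window = max(3L, length(sub) - 1L))
      fl <- piv_segment(stack, n_frames = config$subsample_n,
                        window_px = config$piv_window_px,
                        passes = config$piv_passes)
      list(st = st, fl = fl)
    }, error = function(e) {
      log_line("analyze", sprintf("segment %s skipped: %s", basename(sd),
                                  conditionMessage(e)))
      NULL
    })
    if (is.null(r)) { skipped <- skipped + 1L; next }
    stats_list[[length(stats_list) + 1L]] <- r$st
    flow_list[[length(flow_list) + 1L]] <- r$fl
  }
  if (length(flow_list) == 0L) stop("no segments analyzed", call. = FALSE)
  stats <- do.call(rbind, stats_list)
  flow <- do.call(rbind, flow_list)
  utils::write.csv(stats, file.path(res_dir, "particle_stats.csv"), row.names = FALSE)
  utils::write.csv(flow, file.path(res_dir, "flow.csv"), row.names = FALSE)
  log_line("analyze", sprintf("%d segments analyzed, %d skipped",
                              length(flow_list), skipped))

  correlations <- NULL; psd <- NULL
  tide_csv <- file.path(bundle, "tide.csv")
  if (file.exists(tide_csv)) {
    td <- utils::read.csv(tide_csv)
    tide <- data.frame(time = as.POSIXct(td$timestamp, format = "%Y-%m-%dT%H:%M:%OS",
                                         tz = "UTC"),
                       level = td$level_m)
    class(tide) <- c("tide_series", "data.frame")
    rate <- sea_level_rate(tide, smooth_window_h = config$smooth_rate_h)
    pairs <- align_series(flow, rate)
    axis <- estimate_flow_axis(pairs$direction_deg)
    sflow <- signed_speed(pairs$speed_px_s, pairs$direction_deg, axis)
    ang <- signed_angle(pairs$direction_deg, axis)
    c1 <- pearson_cor(pairs$rate, ang, tag = "rate~signed_angle")
    c2 <- pearson_cor(abs(pairs$rate), pairs$speed_px_s, tag = "abs_rate~speed")
    c3 <- pearson_cor(pairs$rate, sflow, tag = "rate~signed_speed")
    correlations <- list(flow_axis_deg = axis,
                         rate_vs_signed_angle = unclass(c1),
                         abs_rate_vs_speed = unclass(c2),
                         rate_vs_signed_speed = unclass(c3))
    jsonlite::write_json(correlations, file.path(res_dir, "correlations.json"),
                         auto_unbox = TRUE, digits = NA)
    # periodogram of the per-segment particle count at the segment cadence
    cnt <- stats::aggregate(count ~ segment_id, data = stats, FUN = mean)
    if (nrow(cnt) >= 4L) {
      psd <- periodogram_psd(cnt$count, cadence_min = 20)
      utils::write.csv(psd, file.path(res_dir, "psd_count.csv"), row.names = FALSE)
    }
    log_line("correlate", sprintf("axis %.1f deg, r(rate, signed speed) = %.2f",
                                  axis, c3$r))
  }
  spec <- NULL
  wav <- file.path(bundle, "audio.wav")
  if (file.exists(wav)) {
    audio <- read_wav(wav)
    spec <- long_term_spectrogram(audio, fft_size = config$spectrogram$fft_size,
                                  time_resolution_s = config$spectrogram$time_resolution_s,
                                  band = config$spectrogram$band)
    utils::write.csv(data.frame(frequency_hz = spec$frequency_hz,
                                mean_power_db = rowMeans(spec$power_db)),
                     file.path(res_dir, "spectrogram_mean.csv"), row.names = FALSE)
  }
  list(stats = stats, flow = flow, correlations = correlations, psd = psd,
       spectrogram = spec, n_segments_analyzed = length(flow_list),
       results_dir = res_dir)
}
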