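# benthocam

Quantitative analysis of fixed-camera seafloor video and co-recorded
hydrophone audio, aimed at benthic-boundary-layer monitoring deployments:
an upward-looking camera on a mooring records duty-cycled video (e.g.
10-minute VGA files every 20 minutes at 30 fps) under red LED light, while
a recorder samples sound continuously (96 kHz) and a tide gauge provides
sea level at 1-minute cadence.

The package implements the full measurement chain:

* **Suspended-particle quantification** — per-pixel temporal-median
  background estimation, background subtraction, binarization (Otsu with a
  noise floor, or fixed threshold), 8-connected component labelling;
  per frame: particle count, area fraction `A = foreground px / (W x H)`,
  mean RGB intensity, and transient-anomaly flags (first-frame brightness
  spike, lens attachment, sediment glow).
* **Particle image velocimetry (DPIV)** — FFT cross-correlation per
  interrogation window with iterated discrete window offset and 3-point
  Gaussian subpixel peak fitting, normalized-median vector validation, and
  reduction of each video segment to one dominant flow (arithmetic mean of
  magnitudes, circular mean of directions).
* **Tidal correlation** — sea-level rate `d(eta)/dt` (central differences,
  2-h sliding median), alignment of the 20-min flow series with the 1-min
  tide series, circular-to-linear angle handling
  (`signed_angle`, `signed_speed`), Pearson correlations, and raw
  periodograms with chi-squared 95% confidence bounds.
* **Descent profiling** — constant-rate depth mapping of drop footage
  (260 m in 141 s gives 1.84 m/s, i.e. ~6 cm per frame at 30 fps) and the
  RGB-versus-depth attenuation profile with a green/blue extinction depth.
* **Acoustics** — long-term mean spectrogram (Welch, Hann window, 50%
  overlap; defaults 1024-point FFT, 10-s bins, 20 Hz-43 kHz band), plus a
  minimal PCM-16 WAV reader/writer.
* **Detections** — ingestion and summaries of manual-review detection
  tables (counts, integer percentages, mean detection interval) and track
  kinematics for frame-by-frame annotations.
* **Synthetic deployments** — a seeded generator producing an M2 tide with
  spring-neap envelope, tide-driven particle scenes with full ground truth
  (positions, imposed flow, anomaly log), recording schedules, sensor
  logs, descent footage, and tone-plus-noise audio, so every stage is
  testable end to end without the original recordings.

## Worked example

Simulate three tidal days of duty-cycled footage, estimate per-segment
flow by PIV, and correlate it with the sea-level rate:

```r
library(benthocam)

tide <- generate_tide(duration = 72 * 3600, semidiurnal_amp = 1.5, seed = 1)
cfg  <- scene_config(width = 64, height = 48, particle_density = 15,
                     particle_radius = c(1, 3), frames_per_segment = 5,
                     flow_gain = 4, seed = 1)
sch   <- generate_schedule(min(tide$time), total_h = 72)   # 216 segments
scene <- generate_scene(cfg, tide, sch)

flow <- do.call(rbind, lapply(scene$segments, piv_segment,
                              n_frames = 5, window_px = 32, passes = 1))
rate  <- sea_level_rate(tide, smooth_window_h = 2)
pairs <- align_series(flow, rate)
axis  <- estimate_flow_axis(pairs$direction_deg)
pearson_cor(pairs$rate,
            signed_speed(pairs$speed_px_s, pairs$direction_deg, axis))
#> Pearson r(x~y) = 0.983, p = 1.03e-160, n = 216
```

The positive correlation says the particle drift measured from the images
follows the tidal forcing: flow reverses at slack water (flood/ebb
directions ~180 degrees apart) and speeds scale with `|d(eta)/dt|`.
Particle statistics for one segment:

```r
stats <- quantify_segment(scene$segments[[10]], background_window = 4)
head(stats[, c("frame", "count", "area_fraction", "mean_r")], 3)
#>  frame count area_fraction   mean_r
#>      1    12    0.03092448 24.19206
#>      2    10    0.01757812 24.19922
#>      3    10    0.01562500 24.18164
```

Counts track the generated ground truth (the scene above draws a
Poisson(15) particle count per segment); `mean_r` sits just above the
red background level of 12 plus noise, and green/blue means stay near 2.

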