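---
title: "Methods: quantifying near-bed particle dynamics from fixed-camera video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying near-bed particle dynamics from fixed-camera video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(benthocam)
```

## The measurement problem

A mooring carrying an upward-looking camera, red LED lights, and a
hydrophone sits on the seafloor of a tidal fjord. The camera records
duty-cycled video (10-minute VGA files at 30 fps every 20 minutes); the
recorder samples sound continuously at 96 kHz; a shore gauge provides sea
level every minute. From these streams we want physical summaries: how
much suspended matter ("marine snow") is in the water, how it moves, how
that motion relates to the tide, how light decays with depth during the
drop, and what the soundscape looks like over days.

`benthocam` implements that chain as composable, seeded, testable stages.
Because raw deployment video is rarely redistributable, the package also
ships a synthetic-scene generator whose outputs carry complete ground
truth; every processing stage is validated by recovering what the
generator imposed.

## Particle statistics

For each video segment the detection channel is the red channel (under
red LED illumination green and blue carry almost no signal at the
seafloor; during descent a luminance conversion is used instead). The
background is the per-pixel temporal median over a window of frames
(default 30): static or slowly varying structure — the mooring line, the
reflective recorder end-cap, sediment stuck to the lens — survives the
median, while a moving particle occupies any one pixel for only a small
minority of frames and is removed. The first frame of a segment is
excluded from the background window because cameras of this class produce
a power-on brightness spike. Backgrounds are re-estimated per segment;
segments are separated by 10-minute pauses, so no carry-over is assumed.

The residual `max(frame - background, 0)` is binarized. The default
threshold is Otsu's method on the residual histogram with a floor of
10/255: on a residual that contains only sensor noise, Otsu would split
the noise itself, so thresholds below the floor are clipped. A fixed
threshold policy is available for instrument-calibrated work. Components
are labelled with 8-connectivity and components smaller than 2 px are
discarded as single-pixel noise. Touching particles count as one
component — no watershed splitting is attempted, because the downstream
quantities (count, total area) are defined on binarized components. The
area fraction is total component pixels over image pixels
(`A / (W x H)`); mean RGB is computed on the original frame, not the
residual, so it reflects scene radiance rather than detection output.

Three transient-anomaly flags annotate the per-frame series:
`FIRST_FRAME` (frame 1 brighter than the segment median by a configurable
number of robust deviations, default 5 MADs), `ATTACHMENT` (area fraction
jumped above twice its median and stayed there for at least `glow_window`
frames while the largest component's centroid stayed within a few px —
an organism or debris parked on the lens), and `GLOW` (a sustained
near-monotone rise of mean red without a matching rise in particle count —
sediment glow). Flags never remove data; display series are smoothed with
a centered sliding median (3 h at the 20-min segment cadence = 9 samples,
shrinking windows at the edges, missing segments dropped within each
window).

## PIV and the dominant flow

Motion is estimated on background-removed residuals of the first 10
frames of each segment (0.33 s — enough for displacement, cheap enough
for hundreds of files), paired consecutively. Each frame pair is divided
into interrogation windows (default 64 px, 50% overlap, two passes ending
at 32 px). Per window, the displacement is the argmax of the FFT
cross-correlation of the zero-mean windows. Two refinements matter for
accuracy:

* **Iterated discrete window offset.** The second window is re-extracted
  offset by the current integer displacement estimate until the residual
  peak sits at zero lag (near frame edges the offset is split between the
  two windows). At zero lag the correlation peak is symmetric, so the
  subpixel fit is unbiased — and exactly zero for pure integer shifts,
  which is what makes integer-shift recovery exact rather than merely
  close.
* **3-point Gaussian subpixel fit** in x and y (log-parabola through the
  peak and its two neighbors), with a parabolic fallback when a neighbor
  is non-positive. Measured bias on half-pixel displacements of synthetic
  Gaussian particle pairs is ~0.03-0.05 px, within the 0.1 px/component
  budget conventional for DPIV.

Windows with near-zero variance or with a peak correlation coefficient
below 0.25 carry no pattern to match (empty water) and are marked
invalid, not zero. The normalized median test (residual against the
median of up to 8 neighbors, normalized by the neighbors' own median
residual plus 0.1 px, threshold 2) invalidates outliers without
in-filling.

A segment's vector fields reduce to one **dominant flow**: speed is the
arithmetic mean of valid vector magnitudes scaled by fps; direction is
the circular (resultant-vector) mean of vector angles. Circular averaging
is essential — 350 and 10 degrees must average to 0, not 180. Directions
are reported counterclockwise from +x with the y axis up (image rows
flipped). Segments with zero valid vectors yield a missing flow, which
downstream stages drop rather than impute. No px-to-metric calibration is
applied; camera geometry is deployment-specific, so speeds stay in px/s.

## Tidal correlation

The sea-level rate is a central finite difference converted to m/h and
smoothed with a 2-h centered sliding median; feature series for display
use a 3-h median. Flow (20-min cadence) and rate (1-min cadence) are
paired by linear interpolation of the rate to flow timestamps.

Correlating a circular direction with a signed scalar forcing requires
linearization. The deployment's flow axis is estimated as the circular
mean axis of all directions (angles pooled modulo 180 so ebb and flood
reinforce); then either the wrapped signed angle about that axis or the
signed speed `speed * cos(direction - axis)` enters a standard Pearson
correlation with a two-sided t-test p-value. No multiple-testing
correction is applied to the two reported correlations. Periodograms are
raw (untapered, demeaned), with per-ordinate 95% bounds from the
chi-squared(2) sampling distribution of periodogram ordinates, and
frequencies reported per hour.

## Descent profile and acoustics

Assuming a constant descent rate (depth/duration; 260 m in 141 s gives
1.84 m/s), each frame maps to a depth with a vertical resolution of
rate/fps (~6 cm at 30 fps). Channel means are averaged in 1-m bins; the
profile also reports the shallowest depth below which green and blue both
stay under a configurable floor (default 10/255) to the bottom — an
operational "red-only from here down" depth. The floor is a package
choice, not a field-measured constant. Drop-frame identification is an
explicit argument; an automatic heuristic is deliberately not applied
silently.

The long-term spectrogram averages Hann-windowed, 50%-overlap,
`fft_size`-point power spectra (mean, not max) inside coarse time bins
(default 10 s), restricted to a band (default 20 Hz-43 kHz), in dB
re digital full scale — hydrophone sensitivity calibration is out of
scope. The spectrum is window-power normalized so that integrated
spectral density matches the time-domain mean square (checked to 5% for
white noise). WAV I/O is a self-contained PCM-16 RIFF reader/writer.

## The synthetic generator: what it emulates, what it does not

The generator reproduces the *statistical structure the pipeline is
sensitive to*, under the deployment's conditions:

* **Tide**: a single M2 constituent (12.42 h) with a sinusoidal 14.8-day
  spring-neap envelope, amplitude defaulting to 1.5 m. Real tides have
  more constituents; a single dominant semidiurnal is the minimal model
  that produces slack-water reversals and a fortnightly range cycle.
* **Scene**: Gaussian-profile discs (radius 1-4 px, peak brightness
  80-255) on a red-lit background (red ~12, green/blue ~2), advected
  uniformly by `flow_gain x rate(t)` px/frame along a configurable axis
  (default 90 degrees, i.e. flood toward the image top) with independent
  per-particle jitter (sd 0.5 px/frame), plus Gaussian sensor noise
  (sd 3). Counts are Poisson per segment (default mean 85) and particles
  wrap at the frame edges, holding the expected density. A static
  diagonal line and a bright ellipse emulate the mooring rope and
  recorder end-cap. Optional fiber-like elongated particles are off by
  default. The default `flow_gain` of 4 px/frame per m/h makes peak
  spring drift ~3 px/frame — resolvable within a 32-px window.
* **Anomalies**: a first-frame global spike, a static bright lens blob of
  configurable area/duration, and a diffuse ramping glow.
* **Descent**: exponential green/blue decay with depth (e-folding 18 and
  12 m) toward a red-only bottom state.
* **Audio**: sums of sinusoids plus white noise.

Not emulated: photorealistic optics, turbulence and shear (the imposed
field is uniform per frame plus jitter), vortices, particle size/shape
distributions of any real site (the defaults are placeholders, not site
estimates), animal appearances, and codec artifacts (the interchange
format is lossless PNG). Passing recovery tests therefore demonstrates
the *algorithms* are correct and calibrated on their stated model, not
that any field value from a specific deployment is reproduced — field
videos would be required for that, and the two field correlation
coefficients reported for such deployments (~0.5-0.6) are consequently
not targets of the test suite.

## Problem sizes, determinism, and numerical choices

Tests and the acceptance script run the study's temporal design (3-day
deployments, 20-min segment cadence, M2 forcing) at reduced image scale —
64 x 48 to 96 x 72 px frames, 5-15 particles per frame, 5-10 frames per
segment, 32-px single-pass PIV windows — chosen so the full suite runs in
minutes on one core while keeping several particles per interrogation
window, the regime the estimator needs. Generator defaults remain at the
deployment scale (640 x 480, 30 fps, 85 particles).

Every stochastic stage takes an explicit integer seed and restores the
caller's RNG state; fixed seeds give bit-identical scenes, truth tables,
and audio. Degenerate inputs are handled explicitly: zero particle
density yields a valid empty-truth scene; zero tidal amplitude yields a
constant level with zero rate; empty PIV windows and zero-valid-vector
segments yield missing values, never zeros; background windows longer
than a segment are clipped with a warning; threshold floors prevent
noise-only Otsu splits. Ties in the correlation argmax take the first
maximum; angle wrap-around is handled by resultant-vector means
everywhere a mean of angles is needed.

## Known limitations

* Flow speeds are in px/s; comparing speeds across deployments requires
  a camera-geometry calibration the package does not attempt.
* The dominant-flow reduction assumes translational motion; vortical or
  sheared fields reduce to a mean that may not describe any actual
  streamline.
* `ATTACHMENT`/`GLOW` flagging is heuristic and tuned for
  segment-length series; very short segments fall back to the
  first-frame check only.
* The detection-table module summarizes human annotations; it does not
  detect animals in pixels.
* Video containers (MOV/MP4/AVI) are not decoded; segments are exchanged
  as lossless PNG directories with JSON sidecars, which also keeps tests
  codec-deterministic.
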