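---
title: "Methods: simulating and reconstructing event-driven Fourier light field microscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and reconstructing event-driven Fourier light field microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(evlfm)
```

## The imaging model

A Fourier light field microscope places a microlens array at the pupil plane
of a widefield microscope, so the sensor records an array of perspective
sub-images ("views") with uniform angular sampling — here a 5x5 grid, the
configuration of the sensor-format systems this package emulates
(1280x720 px, 4.86 um pitch). An emitter at depth `z` (relative to the
nominal focal plane) appears in view `(u, v)` displaced laterally by
`(u, v) * alpha * z` pixels, where `alpha` (px/um) is the disparity slope set
by the microlens and relay focal lengths. The forward model in
`project_views()` is exactly this shift-and-blur geometry: each z-slice of
the object volume is blurred by a defocus kernel
`sigma(z) = sigma0 * sqrt(1 + (z / z_R)^2)` and shifted per view; the views
are then tiled onto the sensor canvas (`tile_views()`).

This is a geometric, not wave-optical, model: no aberrations, vignetting, or
per-view intensity falloff. The blur law is a defocus-like widening chosen to
reproduce the qualitative axial behavior (growing spot size and parallax away
from focus) without a PSF computed from pupil functions. By default
`z_R` equals half the axial range, so defocus growth is clearly visible
across the supported depth span.

Inversion is the standard light-field refocusing (shift-and-sum):
`refocus_volume()` translates each view by the negative of its forward
disparity and averages, so a source projected at depth `z*` comes back into
register exactly at the slice `z = z*`. Averaging (rather than summing)
keeps the intensity scale independent of the grid size. Subpixel shifts are
bilinear with zero padding; a nearest-neighbour path exists for bit-exact
comparisons against a brute-force oracle. Out-of-focus sources leave a grid
of displaced replicas ("ghosts") in other slices; `threshold_clean()`
suppresses them with a relative threshold (default 10% of the volume
maximum). A pluggable `apply_enhancement()` interface accepts any
volume-to-volume transform for learned post-processing, trained with the
`mae()` / `npcc()` / `total_loss()` objectives (`total = MAE - NPCC`); the
package deliberately ships no trained network.

## The event sensor model

The sensor model (`simulate_events()`) is a per-pixel contrast-threshold
"ladder": each pixel tracks `L(t) = log(I(t) + epsilon)` (linear
interpolation between rendered frames) against a reference level; every
crossing of `reference +- C` emits an event of that sign and advances the
reference to the crossed level. Defaults: `C = 0.25` (~25% contrast, a
typical event-camera bias setting), readout latency drawn uniformly from
100-220 us (the pixel-latency range of the sensor class emulated),
timestamps quantized to 1 us, refractory period equal to each event's own
latency sample, and spontaneous Poisson noise events at 0.1 events/px/s.
`epsilon = 1` intensity unit keeps the log defined at zero background and
plays the role of the sensor's dark floor. The optical sampling interval
used to drive the sensor (default 0.25 ms) must stay at or below half the
accumulation window used downstream; event times are interpolated within a
sampling interval, so an instantaneous step is resolved to sub-interval
precision.

Two consequences of this idealized model matter for everything downstream
and are worth stating bluntly:

* **A static illuminated object emits no events.** Only log-intensity
  *changes* cross thresholds. Real recordings of nominally static targets
  still produce sustained event streams because the illumination itself is
  modulated (DMD refresh, LED driver ripple) and because real pixels have
  threshold mismatch and shot noise. The simulator represents this mechanism
  explicitly: a `stimulus_train()` can carry a square-wave refresh flicker
  (default 1 kHz, 50% depth for spike trains), which is what sustains event
  generation over the ON period of a pulse. Without it, a pulse produces
  only an onset and an offset burst.
* **The event support of an object is approximately binary.** Pixels whose
  per-window log change exceeds `C` fire; others stay silent. Recency maps
  therefore have flat-topped object footprints whose width depends on the
  contrast geometry (and, for moving objects, on speed) rather than tracing
  the graded intensity profile. This is the root cause of the one
  characterization result the simulator does not reproduce (see
  "Known limitations").

## Event-to-frame conversion

`time_surface()` implements the per-pixel exponential time surface: within
an accumulation window `[t_f - delta, t_f]`, the most recent event of the
selected polarity at each pixel is mapped to
`round(255 * exp(-(t_f - t_last) / tau))`; pixels without an event are 0.
Rounding is half-up so golden tests are bit-exact. The window `delta` is
pure post-processing: the same stream converts to 1 kHz frames
(`delta = 1 ms`) or 500 Hz frames (`delta = 2 ms`) without touching the
data, and `frame_sequence()` enforces the exact rate law
`frames = floor(span / delta)`, `rate = 1000 / delta` Hz. Frames are
timestamped at the window's trailing edge.

Parameter guidance, with the reasoning behind the defaults:

* `tau` defaults to `delta / 3`, so an event at the window's far edge decays
  below 5% weight — the time surface then acts as a motion-blur suppressor
  for moving objects.
* For *blinking* targets extracted as temporal traces we instead use
  `tau = 2 * delta`: flicker-sustained responses refresh every flicker
  half-period, and the larger `tau` keeps the sustained plateau above half
  of the onset response, so the trace approximates the stimulus boxcar
  rather than an onset spike train.
* Polarity: `combined` (per-pixel max of the positive and negative surfaces)
  is the default for motion, since leading and trailing edges carry opposite
  signs and both are signal. Blinking and pulse-timing analyses use the
  `positive` surface only: OFF-edge events land just *after* a pulse ends
  and would otherwise light the following frame, breaking pulse timing (a
  1 ms pulse with 2 ms delay must leave exactly two empty frames between
  signal frames).
* Pulse-timing analyses center the accumulation windows on the stimulus
  onsets (acquisition synchronized to the first pulse). The event-time
  interpolation otherwise spreads each onset response across two adjacent
  windows.

`denoise_frame()` is a 2D median filter with replicated edges (3x3 by
default), which removes isolated noise events; the 3x3 path is a vectorized
sorting network validated against a brute-force median in the tests.

## The synthetic scenes

`scene_spec()` describes a time-parameterized 3D fluorescent scene. Beads
are isotropic 3D Gaussians with FWHM equal to their physical diameter
(default 2 um beads, matching the phantom bead size), gated by optional
stimulus trains; trajectories are continuous in time (static, linear with
optional acceleration, or a smooth Ornstein-Uhlenbeck velocity process with
20 ms correlation time for random 3D motion, reflecting at the volume
boundary). The axial extent default of 200 um matches the phantom mold
depth the experiments use; the characterization experiments use thinner
volumes for speed. Background fluorescence is a spatially smoothed positive
random field with a piecewise-linear temporal drift (default +-10% over a
1 s timescale): for a drift timescale at least 100x the accumulation window
the per-window relative change stays below 1%, far under the event
threshold — this slowness is precisely why event-based readout suppresses
scattering background.

What the generator deliberately does not model: optical scattering (only
the slow additive background), worm-body biomechanics (tracked neurons are
independently moving bright blobs), vendor RAW event formats, and
event-rate saturation. Passing tests on these scenes therefore demonstrate
the *algorithmic* chain — contrast sensing, time surfaces, refocusing,
trace/track analysis — not robustness to tissue optics or hardware
artifacts.

## The characterization experiments

Each `experiment_*()` function is a self-contained simulated experiment
with documented problem sizes chosen for desk-top runs (they also set the
scale of the acceptance report):

* `experiment_frame_rate()` — rate law on a 45 ms / 106 ms stream.
* `experiment_snr_gain()` — N identical-signal views with i.i.d. unit
  Gaussian noise, 100 trials, N in {4, 9, 16, 25}; the refocused in-focus
  slice must gain sqrt(N) over a single view. The signal is strong (peak
  100) because the peak-over-sd SNR definition carries an order-statistic
  bias at weak signal that would distort the sqrt(N) law itself.
* `experiment_blink_timing()` — 1 ms pulses, 3 ms period, 45 ms recording
  on a 120x120 sensor (5x5 views of 24 px).
* `experiment_pulse_width()` — widths 1-6 ms, six pulses each, traces from
  the refocused bead ROI, recovered width = FWHM of the spike-triggered
  average.
* `experiment_spike_xcorr()` — 12 static targets on a 3D grid, unique
  random spike trains (widths 1-6 ms, intervals 100-600 ms) over 2.4 s,
  full chain at 1 kHz, Pearson correlation of each ROI trace against each
  binary stimulus waveform at the best lag within one pulse width. Ground
  truth stimuli are ordered by target index.
* `experiment_speed_series()` — one 2 um bead per run at 0.1 / 0.5 / 1.0 /
  2.5 mm/s on a 480x480 sensor (views of 96 px), 1 kHz reconstruction,
  centroid tracking and velocity re-estimation. Observation time per run is
  capped by the FOV transit (~64 um of travel, so the bead never leaves the
  field) and extended for slow beads (240 ms at 0.1 mm/s down to 25 ms at
  2.5 mm/s): the event-starved slow end makes the velocity fit
  variance-limited, and the slope standard error shrinks as observation
  time to the -3/2 power. Detection uses a lateral suppression window wide
  enough (10 um) that a motion-streaked bead yields a single detection, and
  an axial window (12 um) covering the axial elongation of refocused spots.
* `experiment_background_suppression()` — a blinking bead over a
  slowly drifting background (sensor-plane signal-to-background ~1),
  compared against direct intensity frames of the same scene. The
  background level is chosen so the on-pulse log-contrast exceeds the
  event threshold with margin across realizations of the spatial
  background field; a background much brighter than that silences the
  sensor entirely, which is the regime targeted illumination exists to
  avoid.
* `experiment_psf_mtf()` — a bead translating axially at 0.2 mm/s through
  the depth of field under 1 kHz modulated illumination; frames at 1 ms
  intervals become PSF slices 0.2 um apart. The event-derived stack
  (median-denoised) is compared to the direct-intensity stack of *the same
  bead* through the same geometry — physical calibration beads are not
  points, so the reference is not an ideal delta — via the cosine
  similarity of the lateral and axial maximum-intensity projections of the
  two 3D MTFs, the projection-level comparison used to validate spatial
  response. Modulated illumination is essential here: an axially drifting
  bead is quasi-static on the millisecond scale, and an idealized contrast
  sensor would otherwise record almost nothing in the central view.

## Numerical choices

* Coordinates: `x` = column, `y` = row, 0-based in event records; matrices
  are `[row, col]`; `z = 0` at the nominal focal plane. Event timestamps
  are integer microseconds; scene time is floating-point milliseconds.
* Ties in event serialization sort by `(t, y, x, p)`; file reads are
  stable in `t`.
* Time-surface rounding is half-up with a 1e-9 guard so exact half values
  (e.g. one half-life, 127.5) round deterministically to 128.
* Ladder crossing counts use `floor(x + 1e-9)` so a step of exactly `k * C`
  yields `k` events despite floating-point representation.
* The default disparity slope caps the extreme-view shift over the axial
  range at 1/8 of a view tile, avoiding inter-view crosstalk.
* Degenerate inputs: cleanup quantiles are clamped to [0, 1]; frames
  requested before the stream starts are all-zero frames, not errors;
  beads that leave the field of view are flagged in scene metadata, not
  errors.

## Known limitations

* **Resolution stability across speeds.** The measured FWHM of a
  reconstructed bead is stable (within ~10% laterally) across 0.5-2.5 mm/s,
  but at 0.1 mm/s the per-window log-intensity change at the bead rim falls
  below the contrast threshold for most pixels: the event support — and
  with it the apparent width — shrinks. Axially, the elongation of the
  refocused spot grows with the motion per window. Both follow from the
  binarizing nature of an idealized contrast sensor under constant
  illumination; the experimental stability claim this emulates rests on
  graded event generation (noise, threshold mismatch, illumination ripple)
  that the clean threshold model deliberately omits. The characterization
  suite reports the measured variation rather than masking it.
* The time surface here is the documented per-pixel exponential form;
  vendor "built-in" time surfaces with spatial support are not reproduced.
* No deconvolution-based inversion and no trained enhancement network; the
  refocused volume plus the loss interface is the reconstruction surface.
* HDF5 event files are not supported; the CSV dialect (`x,y,t,p`, integer
  microseconds) is the interchange format.

## Problem sizes and reproducibility

All experiment and generator functions take explicit integer seeds and are
bit-reproducible under them. The characterization suite runs on scaled-down
sensors (120x120 to 480x480 pixels, 5x5 views of 24-96 px) and short
recordings (tens of milliseconds to 2.4 s), sizes chosen so the entire
suite completes in minutes on a laptop while every claim is still measured
through the full simulate -> events -> frames -> refocus -> analyze chain.
`scripts/acceptance.R` re-runs all of them from scratch and writes the
measured numbers as JSON.
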