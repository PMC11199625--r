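# evlfm

Event cameras read out asynchronous per-pixel brightness *changes* —
records `(x, y, t, p)` with microsecond timestamps and a polarity sign —
instead of synchronous frames, which removes the frame-rate/field-of-view
trade-off that caps conventional Fourier light field microscopy (LFM) below
~100 Hz. Pairing such a sensor with a Fourier LFM yields single-shot 3D
fluorescence imaging at kilohertz rates: the sensor sees a 5x5 array of
perspective sub-images, and objects at depth `z` shift between views by a
disparity proportional to `z`.

`evlfm` is an R implementation of the complete computational side of such a
system, for microscopists and methods developers who want to build,
exercise, and validate the reconstruction chain on fully synthetic data:

* **Scene simulation** — time-parameterized 3D bead phantoms (linear,
  accelerated, or smooth random 3D motion), blinking and spike-train
  stimuli with millisecond pulse widths, and slowly drifting background
  fluorescence (`make_linear_motion_phantom()`,
  `make_random_motion_phantom()`, `make_pulse_train()`,
  `make_spike_trains()`, `background_spec()`).
* **Optical forward model** — projection of a volume into 5x5 sub-aperture
  views with depth-proportional disparity and defocus blur, tiled onto the
  sensor plane (`project_views()`, `tile_views()`, `system_geometry()`).
* **Event sensor model** — a per-pixel logarithmic contrast-threshold
  ("ladder") model with latency, refractory period, 1 us timestamps, and
  Poisson noise (`simulate_events()`, `sensor_config()`), plus a CSV event
  dialect (`write_events()`, `read_events()`).
* **Reconstruction** — polarity-sorted exponential time surfaces at a
  user-chosen accumulation window (`time_surface()`, `frame_sequence()`;
  1 ms window = 1 kHz frames), median denoising, view cropping, and
  shift-and-sum light field refocusing into 3D volumes
  (`crop_views()`, `refocus_volume()`, `threshold_clean()`).
* **Characterization & analysis** — translating-bead PSF calibration and
  3D MTFs (`psf_from_translating_bead()`, `mtf3d()`), FWHM resolution
  (`fwhm()`, `resolution_report()`), SNR gain of multi-view averaging
  (`snr_gain()`), temporal traces, spike-triggered averages and
  stimulus cross-correlation (`extract_trace()`, `extract_spikes()`,
  `xcorr_matrix()`), 3D centroid tracking and velocity estimation
  (`track_centroids()`, `estimate_velocity()`), and the MAE/NPCC losses
  used for learned volume enhancement (`mae()`, `npcc()`, `total_loss()`).

The refocusing core: the slice at depth `z` is the mean over views of view
`(u, v)` translated by `(-u alpha z, -v alpha z)` pixels, the inverse of the
forward disparity; averaging N views with uncorrelated noise improves SNR
by sqrt(N) — 5x for the 5x5 grid. The time surface assigns each pixel
`round(255 * exp(-(t_f - t_last) / tau))` for the most recent event in the
accumulation window, so the choice of window is pure post-processing and
directly sets the effective frame rate (`1000 / delta_ms` Hz).

## A worked example

One 2 um fluorescent bead moving at 2.5 mm/s is imaged through the 5x5
geometry onto the event sensor, reconstructed at a 1 kHz frame rate, and
tracked in 3D:

```r
library(evlfm)

geom  <- sim_geometry(view_size = 96, z_range = c(-20, 20))
scene <- make_linear_motion_phantom(
  n_beads = 1, extent_um = c(96, 96, 40), thickness_um = 12,
  speed_mm_s = 2.5, duration_ms = 24, direction = c(0, 1, 0),
  voxel_pitch_um = c(1, 1, 2), seed = 7)

stream <- simulate_recording(scene, geom, sensor_config(),
                             dt_sample_ms = 0.25, seed = 7)
stream
#> <event_stream> 157795 events on a 480x480 sensor, t in [3, 24239] us

frame_sequence(stream, delta_ms = 1, t_start_ms = 0, t_end_ms = 24)
#> <frame_sequence> 24 frames at 1000 Hz (window 1 ms)

vols   <- reconstruct_volumes(stream, geom, delta_ms = 1,
                              depths = seq(-15, 15, by = 3),
                              denoise_kernel = 3,
                              t_start_ms = 0, t_end_ms = 24)
tracks <- track_centroids(vols, link_radius_um = 8, threshold_q = 0.35,
                          detect_radius_um = 10, detect_radius_z_um = 12)
tracks
#> # A tibble: 24 x 5
#>      id time_ms  x_um  y_um  z_um
#>   <int>   <dbl> <dbl> <dbl> <dbl>
#> 1     1       1  38.8  7.94  4.71
#> 2     1       2  38.8 10.7   4.67
#> 3     1       3  38.8 13.3   4.68

estimate_velocity(tracks)
#> [1] 2.495
```

The 24 ms event stream converts to 24 one-millisecond time-surface frames
(an effective 1 kHz frame rate); shift-and-sum refocusing places the bead
at its true depth (z ~ 4.7 um here), the track advances ~2.5 um per frame
along y, and the least-squares velocity fit recovers the programmed
2.5 mm/s within 0.2%. `ggplot2::autoplot()` methods exist for frames,
volumes (MIPs), traces, tracks and cross-correlation matrices, and
`write_mip_png()` exports depth color-coded projections.

The higher-level `experiment_*()` functions package the full
characterization suite (frame-rate law, sqrt(N) SNR gain, blink timing,
pulse-width recovery, spike-train cross-correlation, speed series, PSF/MTF
agreement, background suppression); the methods vignette
(`vignettes/event-lfm-methods.Rmd`) documents the models, parameter
defaults, and known limitations.

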