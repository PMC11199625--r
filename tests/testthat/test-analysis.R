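# FWHM, traces, cross-correlation, spikes, tracking, velocity, losses

test_that("fwhm recovers analytic widths and is scale invariant", {
  x <- seq(-30, 30)
  sigma <- 4
  g <- exp(-x^2 / (2 * sigma^2))
  expect_equal(fwhm(g, pitch = 0.5), 2 * sqrt(2 * log(2)) * sigma * 0.5,
               tolerance = 0.01)
  # symmetric triangle of half-width w: FWHM is exactly w * pitch
  tri <- pmax(0, 1 - abs(x) / 8)
  expect_equal(fwhm(tri, pitch = 2), 8 * 2, tolerance = 1e-9)
  expect_equal(fwhm(100 * g, 0.5), fwhm(g, 0.5), tolerance = 1e-12)
  expect_error(fwhm(seq_len(10)), class = "evlfm_no_peak")
  expect_error(fwhm(rep(1, 10)), class = "evlfm_no_peak")
})

test_that("resolution_report measures a rendered bead within 20%", {
  # direct (noise-free) volume of a 2 um bead at fine pitch, small alpha
  geom <- tiny_geometry(view_size = 64, alpha = 0.02, blur_sigma0 = 0.5)
  bead <- bead_object(traj_static(c(16, 16, 10)), radius_um = 2,
                      brightness = 50)
  sc <- scene_spec(list(bead), extent_um = c(32, 32, 20),
                   voxel_pitch_um = c(0.5, 0.5, 0.5), duration_ms = 1)
  vol <- render_intensity(sc, 0.5)
  views <- project_views(vol, geom)
  rv <- refocus_volume(views, geom$alpha, seq(-5, 5, by = 0.5))
  attr(rv, "lateral_um_per_px") <- 0.5
  rep1 <- resolution_report(rv, c(32, 32, 11))
  rendered_fwhm <- 4   # FWHM = bead diameter, um
  expect_lt(abs(rep1$lateral_fwhm_um - rendered_fwhm) / rendered_fwhm, 0.2)
  # intensity scaling leaves the report unchanged
  rv2 <- rv; rv2[] <- 2 * rv[]
  expect_equal(resolution_report(rv2, c(32, 32, 11)), rep1)
})

test_that("traces average the ROI and degenerate cases behave", {
  frames <- lapply(1:4, function(k) matrix(0, 6, 6))
  fs <- structure(list(frames = frames, times_ms = 1:4, delta_ms = 1,
                       frame_rate_hz = 1000), class = "frame_sequence")
  tr <- extract_trace(fs, matrix(TRUE, 6, 6))
  expect_equal(tr$value, rep(0, 4))
  # single-voxel roi equals that voxel's series
  frames2 <- lapply(1:4, function(k) matrix(k, 6, 6) + diag(6))
  fs2 <- structure(list(frames = frames2, times_ms = 1:4, delta_ms = 1,
                        frame_rate_hz = 1000), class = "frame_sequence")
  roi <- matrix(FALSE, 6, 6); roi[2, 2] <- TRUE
  expect_equal(extract_trace(fs2, roi)$value, (1:4) + 1)
  expect_error(extract_trace(fs2, matrix(FALSE, 6, 6)),
               class = "evlfm_invalid_argument")
})

test_that("cross-correlation is 1 on the diagonal for exact traces and matches a direct Pearson loop", {
  times <- seq(1, 400)
  trains <- list(
    stimulus_train(c(50, 150, 250), c(10, 10, 10)),
    stimulus_train(c(100, 300), c(20, 20)))
  traces <- lapply(trains, function(tr) {
    structure(tibble::tibble(time_ms = times,
                             value = stimulus_waveform(tr, times)),
              class = c("trace", class(tibble::tibble())))
  })
  M <- xcorr_matrix(traces, trains)
  expect_equal(diag(unclass(M)), c(1, 1))
  expect_true(all(unclass(M) >= -1 & unclass(M) <= 1))
  # off-diagonal entry against a brute-force Pearson-at-best-lag loop
  v <- traces[[1]]$value; w <- stimulus_waveform(trains[[2]], times)
  best <- 0
  for (lag in -20:20) {
    a <- if (lag >= 0) v[(1 + lag):400] else v[1:(400 + lag)]
    b <- if (lag >= 0) w[1:(400 - lag)] else w[(1 - lag):400]
    r <- cor(a, b)
    if (abs(r) > abs(best)) best <- r
  }
  expect_equal(unclass(M)[1, 2], best)
  # trace scaling leaves the matrix unchanged
  traces2 <- lapply(traces, function(tr) { tr$value <- 7 * tr$value; tr })
  expect_equal(unclass(xcorr_matrix(traces2, trains)), unclass(M))
  # zero-variance trace: NA entry, no error
  traces2[[1]]$value <- rep(1, 400)
  expect_true(is.na(unclass(xcorr_matrix(traces2, trains))[1, 1]))
})

test_that("spike averaging counts snippets and zeroes stderr for identical spikes", {
  times <- seq(1, 200)
  train <- stimulus_train(c(50, 100, 150, 198), rep(2, 4))
  v <- stimulus_waveform(train, times) * 3
  tr <- structure(tibble::tibble(time_ms = times, value = v),
                  class = c("trace", class(tibble::tibble())))
  sp <- extract_spikes(tr, train, peri_window_ms = 10)
  expect_equal(sp$n_spikes, 3)      # the 198 ms onset window is truncated
  expect_true(all(sp$waveform$stderr == 0))
  expect_equal(sp$recovered_width_ms, 2, tolerance = 1)
  off <- stimulus_train(500, 1)
  expect_error(extract_spikes(tr, off, 10),
               class = "evlfm_insufficient_input")
})

test_that("tracking recovers known linear paths against an exhaustive oracle", {
  # two well-separated beads on known linear paths, volumes built directly
  zp <- seq(-10, 10, by = 2)
  mk_vol <- function(p1, p2) {
    vol <- array(0, c(48, 48, length(zp)))
    for (p in list(p1, p2)) {
      iy <- round(p[2]); ix <- round(p[1]); iz <- which.min(abs(zp - p[3]))
      for (dy in -2:2) for (dx in -2:2) {
        vol[iy + dy, ix + dx, iz] <- vol[iy + dy, ix + dx, iz] +
          exp(-(dx^2 + dy^2) / 2)
      }
    }
    structure(vol, z_planes = zp, lateral_um_per_px = 1,
              provenance = list(), class = "refocused_volume")
  }
  t1 <- function(k) c(10 + k, 10 + 0.5 * k, -4 + 0.5 * k)
  t2 <- function(k) c(35 - 0.5 * k, 35, 4)
  vols <- volume_sequence(lapply(0:9, function(k) mk_vol(t1(k), t2(k))), 0:9)
  tracks <- track_centroids(vols, link_radius_um = 5, threshold_q = 0.3,
                            detect_radius_um = 3)
  expect_equal(length(unique(tracks$id)), 2)
  for (k in 0:9) {
    # exhaustive matching oracle: each truth point must have exactly one
    # detection within 1 voxel at each frame
    det <- tracks[tracks$time_ms == k, ]
    for (truth in list(t1(k), t2(k))) {
      d <- sqrt((det$x_um - truth[1])^2 + (det$y_um - truth[2])^2)
      expect_equal(sum(d < 1.5), 1)
    }
  }
  # depth excursion is reproduced in the track z-coordinate
  tr1 <- tracks[tracks$id == tracks$id[which.min(abs(tracks$x_um - 10))], ]
  expect_gt(diff(range(tr1$z_um)), 2)
})

test_that("velocity estimation is exact for clean tracks", {
  tr <- structure(tibble::tibble(id = 1L, time_ms = 0:10,
                                 x_um = 1.5 * (0:10), y_um = 2 * (0:10),
                                 z_um = rep(3, 11)),
                  class = c("track_set", class(tibble::tibble())))
  expect_equal(estimate_velocity(tr), sqrt(1.5^2 + 2^2), tolerance = 1e-9)
  static <- tr; static$x_um <- 0 * static$x_um; static$y_um <- 0
  expect_equal(estimate_velocity(static), 0)
  # accelerating track: late-half speed exceeds early-half speed
  acc <- tr
  acc$x_um <- 0.1 * (0:10) + 0.5 * 0.2 * (0:10)^2
  acc$y_um <- 0; acc$z_um <- 0
  early <- acc[1:5, ]; late <- acc[7:11, ]
  expect_gt(estimate_velocity(late), estimate_velocity(early))
  expect_error(estimate_velocity(tr[1, ]),
               class = "evlfm_insufficient_input")
})

test_that("losses reproduce hand-computed values", {
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mae(c(1, 2, 3) + 4, c(1, 2, 3)), 4)
  expect_equal(mae(c(1, 2, 3), c(2, 2, 5)), 1)
  expect_error(mae(1:4, 1:3), class = "evlfm_invalid_argument")

  expect_equal(npcc(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(npcc(c(1, 2, 3), -c(1, 2, 3)), -1)
  expect_equal(npcc(c(1, 2, 3), c(1, 2, 4)), 0.9820, tolerance = 1e-3)
  # invariance to positive affine transforms
  set.seed(2); a <- rnorm(50); b <- rnorm(50)
  expect_equal(npcc(2 + 3 * a, b), npcc(a, b), tolerance = 1e-12)
  expect_true(abs(npcc(a, b)) <= 1)
  expect_error(npcc(rep(1, 5), 1:5), class = "evlfm_undefined_correlation")

  # perfect prediction scores -1; anti-correlated zero-mean scores mae + 1
  expect_equal(total_loss(c(1, 2, 3), c(1, 2, 3)), -1)
  y <- c(-1, 0, 1)
  expect_equal(total_loss(y, -y), mae(y, -y) + 1)
  # combined loss on one pair, both terms hand-computed:
  # mae = 1, npcc = 3 / (sqrt(2) * sqrt(6)) = 0.8660
  expect_equal(total_loss(c(1, 2, 3), c(2, 2, 5)), 1 - 0.8660,
               tolerance = 1e-3)
})

test_that("the enhancement interface applies volume transforms shape-safely", {
  vol <- structure(array(runif(4 * 4 * 3), c(4, 4, 3)),
                   z_planes = c(-1, 0, 1), lateral_um_per_px = 1,
                   class = "refocused_volume")
  out <- apply_enhancement(vol, function(v) v^2)
  expect_equal(unclass(out), unclass(vol)^2, ignore_attr = TRUE)
  expect_equal(attr(out, "z_planes"), attr(vol, "z_planes"))
  expect_error(apply_enhancement(vol, function(v) v[, , 1]),
               class = "evlfm_invalid_argument")
})
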