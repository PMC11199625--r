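# scene generation: phantoms, stimulus trains, rendering

test_that("linear-motion kinematics follow x(t) = x0 + v t + a t^2 / 2", {
  sc <- make_linear_motion_phantom(1, extent_um = c(64, 64, 40),
                                   thickness_um = 10, speed_mm_s = 2.5,
                                   duration_ms = 6, seed = 3)
  tr <- sc$objects[[1]]$trajectory
  p <- evlfm:::traj_position(tr, c(0, 6))
  # 2.5 mm/s over 6 ms displaces the bead by 15 um
  expect_equal(sqrt(sum((p[2, ] - p[1, ])^2)), 15, tolerance = 1e-9)

  # static case: trajectory constant over time
  sc0 <- make_linear_motion_phantom(1, speed_mm_s = 0, duration_ms = 10,
                                    seed = 1)
  p0 <- evlfm:::traj_position(sc0$objects[[1]]$trajectory, c(0, 5, 10))
  expect_equal(p0[1, ], p0[3, ])

  # accelerating case: v(t) = v0 + a t, checked by numerical differentiation
  # (0.1 mm/s + 2.5 mm/s^2 * 0.96 s = 2.5 mm/s)
  sca <- make_linear_motion_phantom(1, extent_um = c(5000, 5000, 40),
                                    thickness_um = 10, speed_mm_s = 0.1,
                                    accel_mm_s2 = 2.5, duration_ms = 1000,
                                    seed = 1)
  tra <- sca$objects[[1]]$trajectory
  h <- 1e-3
  pp <- evlfm:::traj_position(tra, c(960 - h, 960 + h))
  v_num <- sqrt(sum((pp[2, ] - pp[1, ])^2)) / (2 * h)   # um/ms = mm/s
  expect_equal(v_num, 0.1 + 2.5 * 0.96, tolerance = 1e-6)
})

test_that("phantom generators are deterministic under a seed", {
  a <- make_linear_motion_phantom(5, speed_mm_s = 1, duration_ms = 10,
                                  seed = 42)
  b <- make_linear_motion_phantom(5, speed_mm_s = 1, duration_ms = 10,
                                  seed = 42)
  for (i in 1:5) {
    expect_identical(a$objects[[i]]$trajectory, b$objects[[i]]$trajectory)
  }
  r1 <- make_random_motion_phantom(3, speed_scale_mm_s = 1, duration_ms = 20,
                                   seed = 7)
  r2 <- make_random_motion_phantom(3, speed_scale_mm_s = 1, duration_ms = 20,
                                   seed = 7)
  expect_identical(r1$objects[[2]]$trajectory$positions,
                   r2$objects[[2]]$trajectory$positions)
})

test_that("random-motion beads move smoothly in 3D at the requested RMS speed", {
  sc <- make_random_motion_phantom(5, extent_um = c(400, 400, 200),
                                   speed_scale_mm_s = 1, duration_ms = 2000,
                                   seed = 11)
  # Monte-Carlo RMS speed from the sampled trajectory itself
  speeds2 <- unlist(lapply(sc$objects, function(ob) {
    pos <- ob$trajectory$positions
    dt <- diff(ob$trajectory$times)[1]
    rowSums((diff(pos) / dt)^2)
  }))
  expect_lt(abs(sqrt(mean(speeds2)) - 1), 0.2)
  # distinct trajectories with nonzero depth excursions
  z_ranges <- vapply(sc$objects, function(ob) {
    diff(range(ob$trajectory$positions[, 3]))
  }, numeric(1))
  expect_true(all(z_ranges > 0))
  starts <- vapply(sc$objects,
                   function(ob) paste(ob$trajectory$positions[1, ],
                                      collapse = ","), character(1))
  expect_length(unique(starts), 5)
  expect_error(make_random_motion_phantom(1, speed_scale_mm_s = -1,
                                          duration_ms = 5),
               class = "evlfm_invalid_argument")
})

test_that("pulse trains have the requested period, range, and edge behavior", {
  tr <- make_pulse_train(1, interval = 3, duration_ms = 9)
  expect_equal(tr$onsets, c(0, 3, 6))

  tr2 <- make_pulse_train(1, interval_range = c(2, 50), duration_ms = 500,
                          seed = 5)
  tr2b <- make_pulse_train(1, interval_range = c(2, 50), duration_ms = 500,
                           seed = 5)
  expect_identical(tr2$onsets, tr2b$onsets)
  expect_true(all(diff(tr2$onsets) >= 2 & diff(tr2$onsets) <= 50))

  expect_length(make_pulse_train(2, interval = 5, duration_ms = 1)$onsets, 0)
  expect_error(make_pulse_train(3, interval = 2, duration_ms = 10),
               class = "evlfm_invalid_argument")
})

test_that("spike trains are distinct, in range, and reproducible", {
  trains <- make_spike_trains(12, duration_ms = 2400, seed = 9)
  expect_length(trains, 12)
  for (tr in trains) {
    expect_true(all(tr$widths >= 1 & tr$widths <= 6))
    if (length(tr$onsets) > 1) {
      expect_true(all(diff(tr$onsets) >= 100 & diff(tr$onsets) <= 600))
    }
    expect_gt(max(tr$onsets + tr$widths), 1800)  # spans most of 2.4 s
  }
  sig <- vapply(trains, function(tr) paste(round(tr$onsets, 6),
                                           collapse = ","), character(1))
  expect_length(unique(sig), 12)

  # degenerate ranges are deterministic
  d <- make_spike_trains(1, width_range = c(1, 1),
                         interval_range = c(100, 100), duration_ms = 301,
                         seed = 1)[[1]]
  expect_equal(d$onsets, c(0, 100, 200, 300))
  expect_equal(d$widths, rep(1, 4))

  t2 <- make_spike_trains(3, duration_ms = 1000, seed = 4)
  t3 <- make_spike_trains(3, duration_ms = 1000, seed = 4)
  expect_identical(t2, t3)
  expect_error(make_spike_trains(2, width_range = c(6, 1),
                                 duration_ms = 100),
               class = "evlfm_invalid_argument")
})

test_that("rendering gates beads by their stimulus and sums to the blob mass", {
  train <- stimulus_train(c(2, 6), c(1, 1), amplitude = 0.5)
  bead <- bead_object(traj_static(c(8, 8, 8)), radius_um = 1,
                      brightness = 40, stimulus = train)
  sc <- scene_spec(list(bead), extent_um = c(16, 16, 16), voxel_pitch_um = 1,
                   duration_ms = 10)
  # between pulses: exactly zero
  expect_equal(sum(render_intensity(sc, 4)), 0)
  # inside a pulse: amplitude-scaled blob; oracle = direct triple-loop sum
  vol <- render_intensity(sc, 2.5)
  sigma <- 2 * 1 / (2 * sqrt(2 * log(2)))
  oracle <- 0
  for (x in 1:16) for (y in 1:16) for (z in 1:16) {
    oracle <- oracle + 40 * 0.5 *
      exp(-((x - 0.5 - 8)^2 + (y - 0.5 - 8)^2 + (z - 0.5 - 8)^2) /
            (2 * sigma^2))
  }
  expect_equal(sum(vol), oracle, tolerance = 1e-6)
  # doubling amplitude doubles the rendered blob
  train2 <- stimulus_train(c(2, 6), c(1, 1), amplitude = 1)
  bead2 <- bead_object(traj_static(c(8, 8, 8)), radius_um = 1,
                       brightness = 40, stimulus = train2)
  sc2 <- scene_spec(list(bead2), extent_um = c(16, 16, 16),
                    voxel_pitch_um = 1, duration_ms = 10)
  expect_equal(sum(render_intensity(sc2, 2.5)), 2 * sum(vol),
               tolerance = 1e-9)
  expect_error(render_intensity(sc, 11), class = "evlfm_out_of_range")
})

test_that("slow background drifts by less than 1% per accumulation window", {
  bg <- background_spec(10, drift_timescale_ms = 100, spatial_corr_um = 4)
  sc <- scene_spec(list(), extent_um = c(16, 16, 8), voxel_pitch_um = 1,
                   duration_ms = 50, background = bg, seed = 2)
  v1 <- render_intensity(sc, 20)
  v2 <- render_intensity(sc, 21)     # one 1 ms window later
  rel <- abs(v2 - v1) / pmax(v1, 1e-12)
  expect_lt(max(rel), 0.01)
})

test_that("scene specifications survive a YAML round trip", {
  train <- make_pulse_train(1, interval = 3, duration_ms = 9)
  beads <- list(
    bead_object(traj_linear(c(5, 5, 10), c(0, 1, 0), 1.5), 1, 80, train),
    bead_object(traj_static(c(10, 12, 8)), 2, 50))
  sc <- scene_spec(beads, extent_um = c(24, 24, 20), voxel_pitch_um = 1,
                   duration_ms = 9, seed = 3,
                   background = background_spec(5))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scene_yaml(sc, path)
  sc2 <- read_scene_yaml(path)
  expect_equal(sc2$extent_um, sc$extent_um)
  expect_equal(sc2$objects[[1]]$trajectory$direction,
               sc$objects[[1]]$trajectory$direction)
  expect_equal(sc2$objects[[1]]$stimulus$onsets, train$onsets)
  expect_equal(sc2$background$mean_level, 5)
  t_test <- c(0, 2.5, 7)
  expect_equal(render_intensity(sc2, 2.5), render_intensity(sc, 2.5))
})
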