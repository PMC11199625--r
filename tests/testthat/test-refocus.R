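# view cropping, shift-and-sum refocusing, PSF/MTF, SNR gain

test_that("view centers come from geometry exactly and from data within 0.5 px", {
  geom <- tiny_geometry()
  ctr <- calibrate_view_centers(geom)
  expect_equal(nrow(ctr), 25)
  expect_equal(sort(unique(diff(sort(unique(ctr$col_c))))), 32)
  # data path: detect spots on a synthetic focal PSF frame
  frame <- synth_psf_stack(geom, 0)$images[[1]]
  est <- calibrate_view_centers(frame, grid_side = 5)
  truth <- ctr[order(ctr$v, ctr$u), ]
  got <- est[order(est$v, est$u), ]
  expect_lte(max(abs(got$row_c - truth$row_c)), 0.5 + 1e-9)
  expect_lte(max(abs(got$col_c - truth$col_c)), 0.5 + 1e-9)
  # too few spots -> calibration failure reporting the count
  expect_error(calibrate_view_centers(matrix(0, 50, 50), grid_side = 5),
               class = "evlfm_calibration_error")
})

test_that("cropping a tiled frame recovers the original views", {
  geom <- tiny_geometry()
  set.seed(5)
  arr <- array(runif(32 * 32 * 25), c(32, 32, 5, 5))
  views <- structure(arr, uv = -2:2, lateral_um_per_px = 1,
                     class = "view_set")
  img <- tile_views(views, geom)
  ctr <- calibrate_view_centers(geom)
  back <- crop_views(img, ctr)
  expect_equal(unclass(back), unclass(views), ignore_attr = TRUE)
  expect_equal(dim(back)[3] * dim(back)[4], 25)
  # crop then re-tile restores the frame inside the tiles
  expect_equal(tile_views(back, geom), img)
  # out-of-bounds crop names the offending view
  bad <- ctr
  bad$col0[1] <- 10^4
  expect_error(crop_views(img, bad), class = "evlfm_invalid_argument")
})

test_that("refocusing equals the brute-force shift-and-sum oracle for integer shifts", {
  geom <- tiny_geometry(alpha = 0.2)
  set.seed(6)
  arr <- array(runif(32 * 32 * 25), c(32, 32, 5, 5))
  views <- structure(arr, uv = -2:2, lateral_um_per_px = 1,
                     class = "view_set")
  depths <- c(-10, -5, 0, 5, 10)        # alpha * z integer for all
  vol <- refocus_volume(views, 0.2, depths, interp = "nearest")
  oracle <- refocus_oracle(views, 0.2, depths)
  expect_identical(unclass(vol)[, , ], oracle[, , ])
  # alpha = 0: every slice is the plain mean of views
  v0 <- refocus_volume(views, 0, c(-3, 3))
  mean_view <- apply(arr, c(1, 2), mean)
  expect_equal(v0[, , 1], mean_view, tolerance = 1e-12)
  expect_equal(v0[, , 2], mean_view, tolerance = 1e-12)
  # linearity in the views
  views2 <- structure(2 * arr, uv = -2:2, lateral_um_per_px = 1,
                      class = "view_set")
  expect_equal(unclass(refocus_volume(views2, 0.2, depths,
                                      interp = "nearest")),
               2 * unclass(vol), ignore_attr = TRUE)
  expect_error(refocus_volume(views, 0.2, numeric(0)),
               class = "evlfm_invalid_argument")
})

test_that("a point source refocuses to its true depth across the z-range", {
  geom <- tiny_geometry(alpha = 0.2, blur_sigma0 = 1)
  ctr <- calibrate_view_centers(geom)
  depths <- seq(-9, 9, by = 1.5)
  for (z_true in c(-7.5, -3, 0, 4.5, 9)) {
    vw <- project_views(point_volume(32, z_true), geom)
    img <- tile_views(vw, geom)
    vol <- refocus_volume(crop_views(img, ctr), geom$alpha, depths)
    peak_z <- depths[which.max(apply(unclass(vol), 3, max))]
    expect_lte(abs(peak_z - z_true), 1.5)   # within one z-step
  }
})

test_that("threshold cleanup suppresses refocusing ghosts, not the peak", {
  geom <- tiny_geometry(alpha = 0.2, blur_sigma0 = 1)
  ctr <- calibrate_view_centers(geom)
  vw <- project_views(point_volume(32, 6), geom)
  vol <- refocus_volume(crop_views(tile_views(vw, geom), ctr), geom$alpha,
                        c(-6, 0, 6))
  # ghost level: max over the out-of-focus slices
  ghost_before <- max(vol[, , 1:2]) / max(vol)
  cleaned <- threshold_clean(vol, q = 0.5)
  ghost_after <- max(cleaned[, , 1:2]) / max(cleaned)
  expect_lt(ghost_after, ghost_before)
  expect_equal(max(cleaned), max(vol))
  # q = 0 is the identity; q = 1 keeps only the global maximum
  expect_equal(unclass(threshold_clean(vol, 0)), unclass(vol),
               ignore_attr = TRUE)
  top <- threshold_clean(vol, 1)
  expect_equal(sum(top > 0), sum(vol == max(vol)))
})

test_that("translating-bead PSF slices are spaced by speed x window", {
  st <- moving_bead_stream(speed_mm_s = 1, duration_ms = 20, seed = 4)
  ps <- psf_from_translating_bead(st, axial_speed_mm_s = 0.2, delta_ms = 1)
  expect_equal(unique(round(diff(ps$depths_um), 9)), 0.2)
  # doubling the speed halves the slice count over the same stream span
  ps2 <- psf_from_translating_bead(st, 0.4, delta_ms = 2)
  expect_equal(unique(round(diff(ps2$depths_um), 9)), 0.8)
  expect_equal(length(ps2$depths_um), length(ps$depths_um) %/% 2)
  short <- stream_of(data.frame(x = 1, y = 1, t = c(0, 100), p = 1L))
  expect_error(psf_from_translating_bead(short, 0.2, delta_ms = 1),
               class = "evlfm_insufficient_input")
})

test_that("the 3D MTF matches analytic Fourier pairs", {
  # delta PSF -> flat MTF, exactly 1 everywhere
  delta <- array(0, c(8, 8, 8)); delta[3, 5, 2] <- 4
  M <- mtf3d(delta)
  expect_true(all(abs(M - 1) < 1e-12))
  # isotropic Gaussian PSF -> Gaussian MTF with sigma_f = 1 / (2 pi sigma)
  n <- 32; sigma <- 2
  ax <- seq_len(n) - (n / 2 + 1)
  g1 <- exp(-ax^2 / (2 * sigma^2))
  psf <- outer(outer(g1, g1), g1)
  M <- mtf3d(psf)
  f <- attr(M, "freq")[[1]]
  pred <- exp(-2 * pi^2 * sigma^2 * f^2)
  mid <- n / 2 + 1
  expect_lt(max(abs(M[, mid, mid] - pred)), 1e-6)
  expect_lt(max(abs(M[mid, , mid] - pred)), 1e-6)
  # zero frequency exactly 1; symmetry under frequency negation
  expect_equal(M[mid, mid, mid], 1)
  expect_equal(M[mid + 3, mid - 2, mid + 1], M[mid - 3, mid + 2, mid - 1],
               tolerance = 1e-9)
  expect_error(mtf3d(array(0, c(4, 4, 4))), class = "evlfm_invalid_argument")
})

test_that("SNR gain follows sqrt(N) and degenerates to 1 for one view", {
  g <- experiment_snr_gain(grid_sides = c(2, 5), n_trials = 40, seed = 12)
  expect_equal(g$gain, g$expected, tolerance = 0.05)
  # single view: gain exactly 1
  set.seed(1)
  one <- structure(array(100 + rnorm(32 * 32), c(32, 32, 1, 1)), uv = 0,
                   lateral_um_per_px = 1, class = "view_set")
  slice <- refocus_volume(one, 0, 0)[, , 1]
  sig <- matrix(FALSE, 32, 32); sig[14:18, 14:18] <- TRUE
  bg <- matrix(FALSE, 32, 32); bg[1:6, ] <- TRUE
  expect_equal(snr_gain(one, slice, sig, bg), 1)
  flat <- structure(array(1, c(32, 32, 1, 1)), uv = 0,
                    lateral_um_per_px = 1, class = "view_set")
  expect_error(snr_gain(flat, flat[, , 1, 1], sig, bg),
               class = "evlfm_undefined_snr")
  expect_error(snr_gain(one, slice, sig, sig),
               class = "evlfm_invalid_argument")
})

test_that("event-derived and direct-intensity MTFs agree at the projection level", {
  p <- experiment_psf_mtf(speed_mm_s = 0.2, seed = 13)
  expect_gte(p$cosine, 0.9)
  expect_equal(unique(round(diff(p$event_psf$depths_um), 9)), 0.2)
})
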