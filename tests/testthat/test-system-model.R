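test_that("HU to density follows the piecewise-linear segment table", {
  am <- attenuation_model()
  ct <- volume_grid(array(c(-1000, 0, 500, 1000, -200, 250),
                          c(6, 1, 1)), c(4, 4, 4))
  d <- hu_to_density(ct, am)$data
  expect_equal(d[1], 0)        # air anchor
  expect_equal(d[2], 1.0)      # water anchor
  expect_equal(d[4], 1.55)
  # interpolation against the two-point formula
  expect_equal(d[3], 1.0 + (1.55 - 1.0) * 500 / 1000)
  expect_equal(d[5], 0 + (1.0 - 0) * (-200 - -1000) / 1000)
  expect_equal(d[6], 1.0 + (1.55 - 1.0) * 250 / 1000)
  expect_error(attenuation_model(hu_breakpoints = c(0, 0, 10),
                                 densities = c(0, 1, 1)), "increasing")
})

test_that("density to attenuation thresholds materials voxel-wise", {
  am <- attenuation_model(material_threshold = 1.15,
                          mass_attenuation = c(soft = 0.136, bone = 0.146))
  den <- volume_grid(array(c(0, 1.0, 1.0, 1.4), c(2, 2, 1)), c(4, 4, 4))
  mu <- density_to_attenuation(den, am)$data
  expect_equal(mu[1, 1, 1], 0)
  expect_equal(mu[2, 1, 1], 1.0 * 0.136)
  expect_equal(mu[2, 2, 1], 1.4 * 0.146)
  # two-material slab has exactly two distinct non-zero mu values
  slab <- volume_grid(array(rep(c(1.0, 1.6), each = 8), c(4, 4, 1)),
                      c(4, 4, 4))
  vals <- unique(as.vector(density_to_attenuation(slab, am)$data))
  expect_length(vals, 2L)
})

test_that("PSF kernels are normalized with the geometric FWHM model", {
  rm <- resolution_model(hole_diameter_mm = 3, effective_hole_length_mm = 55,
                         intrinsic_fwhm_mm = 3.9)
  # FWHM at d = 0 equals sqrt(intrinsic^2 + hole^2); monotone in distance
  expect_equal(psf_fwhm(0, rm), sqrt(3.9^2 + 3^2))
  ds <- seq(0, 400, by = 25)
  expect_true(all(diff(psf_fwhm(ds, rm)) > 0))
  for (d in c(0, 100, 250)) {
    k <- psf_kernel(d, rm, c(4.42, 4.42))
    expect_equal(sum(k), 1, tolerance = 1e-12)
    expect_true(all(k >= 0))
  }
  # discrete kernel second moment reproduces the analytic FWHM at 250 mm
  k <- psf_kernel(250, rm, c(4.42, 4.42))
  i <- seq_len(nrow(k)) - (nrow(k) + 1) / 2
  marg <- rowSums(k)
  sigma_px <- sqrt(sum(marg * i^2))
  fwhm_meas <- sigma_px * 4.42 * 2 * sqrt(2 * log(2))
  expect_lt(abs(fwhm_meas / psf_fwhm(250, rm) - 1), 0.05)
  expect_error(resolution_model(effective_hole_length_mm = 0), "> 0")
  expect_identical(psf_kernel(100, resolution_model(enabled = FALSE),
                              c(4.42, 4.42)), matrix(1, 1, 1))
})

test_that("effective scatter source conserves amplitude-scaled totals", {
  sm <- scatter_model(amplitude = 0.25, decay_mm = 20)
  n <- 48
  act <- array(0, c(n, n, n)); act[20:28, 20:28, 20:28] <- 2
  av <- volume_grid(act, c(4.42, 4.42, 4.42))
  ss <- scatter_source(av, sm)
  expect_lt(abs(sum(ss$effective_source$data) / (0.25 * sum(act)) - 1), 1e-3)
  # point source reproduces the kernel shape (scaled)
  sm8 <- scatter_model(amplitude = 0.25, decay_mm = 8)
  pt <- array(0, c(33, 33, 33)); pt[17, 17, 17] <- 1
  ssp <- scatter_source(volume_grid(pt, c(4.42, 4.42, 4.42)), sm8)
  kern <- rvspect:::scatter_kernel_3d(sm8, c(4.42, 4.42, 4.42))
  h <- (dim(kern) - 1) / 2
  sub <- ssp$effective_source$data[17 + (-h[1]:h[1]), 17 + (-h[2]:h[2]),
                                   17 + (-h[3]:h[3])]
  expect_equal(sub, 0.25 * kern, tolerance = 1e-8)
  # disabled model gives a zero source
  off <- scatter_model(enabled = FALSE)
  expect_true(all(scatter_source(av, off)$effective_source$data == 0))
})

test_that("mean-scatter-energy mode rescales the scatter attenuation path", {
  n <- 16
  set.seed(6)
  act <- volume_grid(array(runif(n^3), c(n, n, n)), c(4.42, 4.42, 4.42))
  mu <- volume_grid(array(0.012, c(n, n, n)), c(4.42, 4.42, 4.42))
  geom <- acquisition_geometry(n_views = 4, orbit_radius_mm = 150,
                               pixel_size_mm = c(4.42, 4.42),
                               detector_shape = c(n, n), time_per_view_s = 5)
  sm <- scatter_model(amplitude = 0.3, decay_mm = 20,
                      mean_scatter_energy_mode = TRUE,
                      scatter_energy_mu_scale = 1.2)
  w <- scatter_source(act, sm)$mean_energy_weight
  expect_true(all(w$data >= 0 & w$data <= 1))
  P_mean <- forward_project(act, mu, geom, NULL, sm, 1)
  sm_off <- sm; sm_off$mean_scatter_energy_mode <- FALSE
  P_photo <- forward_project(act, mu, geom, NULL, sm_off, 1)
  # a larger mu along the scatter path can only reduce scatter counts
  expect_lte(sum(P_mean$counts), sum(P_photo$counts))
  expect_gt(sum(P_photo$counts) - sum(P_mean$counts), 0)
})

test_that("forward projection conserves counts and is linear in the source", {
  set.seed(10)
  geom <- small_geometry(n = 32L, n_views = 8L)
  x <- disc_source(32)
  P <- forward_project(x, NULL, geom, NULL, NULL, calibration = 5)
  expected <- total_activity(x) * geom$time_per_view_s * 5
  per_view <- apply(P$counts, 3, sum)
  expect_true(all(abs(per_view / expected - 1) < 0.01))
  # single-voxel source at the rotation centre, one view
  g1 <- small_geometry(n = 32L, n_views = 1L)
  x1 <- array(0, c(32, 32, 32)); x1[16, 16, 16] <- 3.7
  P1 <- forward_project(volume_grid(x1, c(4.42, 4.42, 4.42)), NULL, g1,
                        NULL, NULL, calibration = 5)
  expect_lt(abs(sum(P1$counts) /
                  (3.7 * 4.42^3 / 1000 * g1$time_per_view_s * 5) - 1), 0.005)
  # linearity with scatter included
  y <- disc_source(32)
  scat <- scatter_model(amplitude = 0.2, decay_mm = 25)
  mu <- volume_grid(array(0.01, c(32, 32, 32)), c(4.42, 4.42, 4.42))
  res <- resolution_model()
  A <- function(v) forward_project(v, mu, geom, res, scat, 5)$counts
  comb <- volume_grid(2 * x$data + 3 * y$data, x$voxel_size)
  expect_equal(A(comb), 2 * A(x) + 3 * A(y), tolerance = 1e-6)
})

test_that("attenuation follows Beer-Lambert against a ray-traced oracle", {
  n <- 32
  vs <- c(4.42, 4.42, 4.42)
  g1 <- small_geometry(n = n, n_views = 1L)  # view at 0 degrees
  src <- array(0, c(n, n, n)); src[16, 10, 16] <- 1
  mu_arr <- array(0, c(n, n, n))
  mu_arr[, 14:20, ] <- 0.015  # slab between source and detector (+y)
  P0 <- forward_project(volume_grid(src, vs), NULL, g1, NULL, NULL, 1)
  P1 <- forward_project(volume_grid(src, vs),
                        volume_grid(mu_arr, vs), g1, NULL, NULL, 1)
  # independent line integral from voxel 10 toward +y with half-voxel self
  path <- sum(mu_arr[16, 11:n, 16]) * 0.442 + 0.5 * mu_arr[16, 10, 16] * 0.442
  expect_equal(sum(P1$counts) / sum(P0$counts), exp(-path), tolerance = 1e-10)
})

test_that("back-projection of uniform projections is rotationally symmetric", {
  geom <- small_geometry(n = 32L, n_views = 60L)
  ones <- projection_set(array(1, c(32, 32, 60, 1)), geom)
  bp <- back_project(ones, NULL, NULL, calibration = 1)
  sl <- bp$data[, , 16]
  co <- (1:32) - 16.5
  r <- sqrt(outer(co^2, co^2, "+"))
  th <- atan2(outer(co * 0, co, "+"), outer(co, co * 0, "+"))
  band <- r >= 4 & r <= 12.8  # inside 80% of the FOV radius
  sect <- cut(th[band], breaks = seq(-pi, pi, length.out = 9))
  ms <- tapply(sl[band], sect, mean)
  expect_lt((max(ms) - min(ms)) / mean(ms), 0.02)
  # all-zero projections give an all-zero accumulation
  z <- back_project(projection_set(array(0, c(32, 32, 60, 1)), geom), NULL, NULL)
  expect_true(all(z$data == 0))
})

test_that("detector mask zeroes masked pixels in both directions", {
  n <- 16
  mask <- matrix(TRUE, n, n); mask[, c(1:3, 14:16)] <- FALSE
  geom <- acquisition_geometry(n_views = 4, orbit_radius_mm = 150,
                               pixel_size_mm = c(4.42, 4.42),
                               detector_shape = c(n, n),
                               time_per_view_s = 5, detector_mask = mask)
  set.seed(2)
  x <- volume_grid(array(runif(n^3), c(n, n, n)), c(4.42, 4.42, 4.42))
  P <- forward_project(x, NULL, geom, NULL, NULL, 1)
  expect_true(all(P$counts[, c(1:3, 14:16), , ] == 0))
  expect_gt(sum(P$counts), 0)
})

test_that("multi-bed projections shift the source axially per bed", {
  n <- 16
  geom <- acquisition_geometry(n_views = 1, orbit_radius_mm = 150,
                               pixel_size_mm = c(4.42, 4.42),
                               detector_shape = c(n, n), time_per_view_s = 5,
                               bed_axial_offsets_mm = c(0, 2 * 4.42))
  x <- array(0, c(n, n, n)); x[8, 8, 8] <- 1
  P <- forward_project(volume_grid(x, c(4.42, 4.42, 4.42)), NULL, geom,
                       NULL, NULL, 1)
  p1 <- P$counts[, , 1, 1]; p2 <- P$counts[, , 1, 2]
  # bed 2 sees the source two detector rows lower
  expect_equal(which(p1 == max(p1), arr.ind = TRUE)[1, 2] - 2,
               which(p2 == max(p2), arr.ind = TRUE)[1, 2])
  expect_equal(sum(p1), sum(p2), tolerance = 1e-12)
})

test_that("geometry validation rejects inconsistent inputs", {
  expect_error(acquisition_geometry(angles = c(0, 400), n_views = 2), "360")
  expect_error(acquisition_geometry(orbit_radius_mm = -1), "> 0")
  expect_error(acquisition_geometry(time_per_view_s = 0), "> 0")
  geom <- small_geometry(n = 16L, n_views = 2L)
  expect_error(projection_set(array(1, c(8, 8, 2, 1)), geom), "inconsistent")
  expect_error(projection_set(array(-1, c(16, 16, 2, 1)), geom), ">= 0")
  x <- volume_grid(array(1, c(16, 16, 16)), c(2, 2, 2))
  expect_error(forward_project(x, NULL, geom, NULL, NULL), "pixel size")
  mu_bad <- volume_grid(array(-0.1, c(16, 16, 16)), c(4.42, 4.42, 4.42))
  xo <- volume_grid(array(1, c(16, 16, 16)), c(4.42, 4.42, 4.42))
  expect_error(forward_project(xo, mu_bad, geom, NULL, NULL), ">= 0")
})
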