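test_that("em_update reproduces hand-computed EM arithmetic on a 2x2 system", {
  A <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, 2, byrow = TRUE)
  x_true <- c(2, 5)
  y <- as.vector(A %*% x_true)
  fwd <- function(x) as.vector(A %*% x)
  bwd <- function(r) as.vector(t(A) %*% r)
  sens <- bwd(c(1, 1))
  x <- c(1, 1)
  # hand-computed first update
  yhat <- as.vector(A %*% x)
  hand <- x * as.vector(t(A) %*% (y / yhat)) / sens
  expect_identical(em_update(x, y, fwd, bwd, sens), hand)
  # iterating EM converges to the exact solution of this invertible system
  for (i in 1:500) x <- em_update(x, y, fwd, bwd, sens)
  expect_equal(x, x_true, tolerance = 1e-6)
  # zero-sensitivity elements are frozen
  sens0 <- c(sens[1], 0)
  x2 <- em_update(c(1, 1), y, fwd, bwd, sens0)
  expect_equal(x2[2], 1)
})

test_that("MLEM log-likelihood is non-decreasing on noise-free data", {
  ph <- two_region_phantom(ni = c(32, 32, 32), fac = c(1, 1, 1),
                           vs_i = c(4.42, 4.42, 4.42))
  geom <- acquisition_geometry(n_views = 12, orbit_radius_mm = 200,
                               pixel_size_mm = c(4.42, 4.42),
                               detector_shape = c(32L, 32L),
                               time_per_view_s = 10)
  truth <- source_model(ph$activity, ph$region_map, c(1, 1, 1), "rv")
  mu <- density_to_attenuation(ph$density)
  res <- resolution_model()
  clean <- forward_project(truth, mu, geom, res, NULL, calibration = 10)
  tmpl <- source_model(volume_grid(array(1, dim(ph$activity$data)),
                                   ph$activity$voxel_size),
                       emulated_factor = c(1, 1, 1), mode = "cuv")
  fit <- osem(clean, mu, res, NULL, tmpl,
              recon_config(n_iterations = 50L, n_subsets = 1L,
                           convergence_log = TRUE), calibration = 10)
  ll <- fit$convergence$log_likelihood
  expect_true(all(diff(ll) > -abs(ll[1]) * 1e-10))
})

test_that("OS-EM is deterministic and respects the subset stride ordering", {
  ph <- two_region_phantom(ni = c(32, 32, 32), fac = c(1, 1, 1),
                           vs_i = c(4.42, 4.42, 4.42))
  geom <- acquisition_geometry(n_views = 12, orbit_radius_mm = 200,
                               pixel_size_mm = c(4.42, 4.42),
                               detector_shape = c(32L, 32L),
                               time_per_view_s = 10)
  truth <- source_model(ph$activity, ph$region_map, c(1, 1, 1), "rv")
  clean <- forward_project(truth, NULL, geom, NULL, NULL, 5)
  noisy <- add_poisson_noise(clean, 21)
  tmpl <- source_model(volume_grid(array(1, dim(ph$activity$data)),
                                   ph$activity$voxel_size),
                       ph$region_map, c(1, 1, 1), "rv")
  cfg <- recon_config(n_iterations = 3L, n_subsets = 4L)
  f1 <- osem(noisy, NULL, NULL, NULL, tmpl, cfg)
  f2 <- osem(noisy, NULL, NULL, NULL, tmpl, cfg)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(rvspect:::subset_views(12, 4),
                   list(c(1L, 5L, 9L), c(2L, 6L, 10L), c(3L, 7L, 11L),
                        c(4L, 8L, 12L)))
  # all estimates stay non-negative
  expect_true(all(f1$source$internal$data >= 0))
})

test_that("noise-free r.v. reconstruction reproduces regional truth (inverse crime)", {
  ph <- two_region_phantom()
  geom <- acquisition_geometry(n_views = 30, orbit_radius_mm = 200,
                               pixel_size_mm = c(4.42, 4.42),
                               detector_shape = c(32L, 16L),
                               time_per_view_s = 10)
  truth <- source_model(ph$activity, ph$region_map, c(2, 2, 1), "rv")
  mu <- density_to_attenuation(downsample_to_emulated(ph$density, c(2, 2, 1)))
  res <- resolution_model()
  clean <- forward_project(truth, mu, geom, res, NULL, calibration = 10)
  tmpl <- source_model(volume_grid(array(1, dim(ph$activity$data)),
                                   ph$activity$voxel_size),
                       ph$region_map, c(2, 2, 1), "rv")
  fit <- osem(clean, mu, res, NULL, tmpl,
              recon_config(n_iterations = 8L, n_subsets = 10L),
              calibration = 10)
  est <- extract_estimates(fit$source)
  truthm <- region_average(ph$activity, ph$region_map)$means
  expect_true(all(abs(est$concentration /
                        truthm[as.character(est$label)] - 1) < 0.005))
  # internal representation is exactly region-wise constant
  for (l in est$label) {
    vals <- fit$source$internal$data[ph$region_map$labels == l]
    expect_equal(max(vals) - min(vals), 0)
  }
  # total projected counts of the converged solution match the data total
  P <- forward_project(fit$source, mu, geom, res, NULL, 10)
  expect_lt(abs(sum(P$counts) / sum(clean$counts) - 1), 0.01)
})

test_that("calibration factor is consistent and scales with acquisition time", {
  # uniform cylinder (5.6 L scale-down) with a central VOI
  n <- 32; vs <- c(4.42, 4.42, 4.42)
  co <- ((1:n) - (n + 1) / 2) * 4.42
  cyl <- outer(outer(co^2, co^2, "+"), co * 0, "+") <= 60^2
  act <- array(0.1 * cyl, c(n, n, n))
  av <- volume_grid(act, vs)
  voi <- outer(outer(co^2, co^2, "+"), co * 0 + 1, "*") <= 30^2 &
    outer(outer(co * 0, co * 0, "+"), abs(co) <= 30, "+") > 0
  geom <- small_geometry(n = 32L, n_views = 12L, time = 10)
  run <- function(time_s, cal_true) {
    g <- geom; g$time_per_view_s <- time_s
    clean <- forward_project(av, NULL, g, NULL, NULL, calibration = cal_true)
    # reconstruct against a reference-time geometry with unit sensitivity;
    # the calibration factor then absorbs both the true sensitivity and
    # the acquisition-time ratio
    g_ref <- geom  # time 10 s
    ps <- projection_set(clean$counts, g_ref)
    tmpl <- source_model(volume_grid(array(1, c(n, n, n)), vs), mode = "cuv")
    fit <- osem(ps, NULL, NULL, NULL, tmpl,
                recon_config(n_iterations = 10L, n_subsets = 4L),
                calibration = 1)
    calibrate(emulated_volume(fit$source), voi, true_concentration = 0.1)
  }
  f1 <- run(10, 8)
  expect_lt(abs(f1$value / 8 - 1), 0.05)
  # doubling the simulated acquisition time doubles the factor
  f2 <- run(20, 8)
  expect_lt(abs(f2$value / f1$value / 2 - 1), 0.02)
  # applying the factor returns the true concentration (circularity)
  expect_error(calibrate(av, array(FALSE, c(n, n, n)), 0.1), "empty")
})

test_that("bootstrap reconstruction: identical realizations give zero SD; organ SDs are small", {
  ph <- two_region_phantom()
  geom <- acquisition_geometry(n_views = 20, orbit_radius_mm = 200,
                               pixel_size_mm = c(4.42, 4.42),
                               detector_shape = c(32L, 16L),
                               time_per_view_s = 45)
  truth <- source_model(ph$activity, ph$region_map, c(2, 2, 1), "rv")
  clean <- forward_project(truth, NULL, geom, NULL, NULL, calibration = 10)
  noisy <- add_poisson_noise(clean, 3)
  tmpl <- source_model(volume_grid(array(1, dim(ph$activity$data)),
                                   ph$activity$voxel_size),
                       ph$region_map, c(2, 2, 1), "rv")
  cfg <- recon_config(n_iterations = 4L, n_subsets = 10L)
  ests <- reconstruct_bootstrap(list(noisy, noisy, noisy), NULL, NULL, NULL,
                                tmpl, cfg, calibration = 10)
  tab <- do.call(rbind, ests)
  s <- vapply(split(tab$concentration, tab$label), sd, numeric(1))
  expect_true(all(s == 0))
  # organ-scale SD/mean over bootstrap realizations is small
  set <- bootstrap_realizations(noisy, n_bins = 15, n_realizations = 8,
                                seed = 9)
  ests2 <- reconstruct_bootstrap(set, NULL, NULL, NULL, tmpl, cfg,
                                 calibration = 10)
  tab2 <- do.call(rbind, ests2)
  organ <- tab2[tab2$label == 2L, ]
  expect_lt(sd(organ$concentration) / mean(organ$concentration), 0.05)
  # mean over realizations is consistent with the noise-free estimate
  nf <- reconstruct_bootstrap(list(clean), NULL, NULL, NULL, tmpl, cfg,
                              calibration = 10)[[1]]
  nf_c <- nf$concentration[nf$label == 2L]
  se <- sd(organ$concentration) / sqrt(nrow(organ))
  expect_lt(abs(mean(organ$concentration) - nf_c), max(4 * se, 0.02 * nf_c))
})
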