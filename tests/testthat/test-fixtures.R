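test_that("make_phantom paints co-registered volumes with voxel-centre membership", {
  spec <- phantom_spec(c(64, 64, 64), c(4.42, 4.42, 4.42),
                       bodies = list(list(shape = "sphere", center = c(0, 0, 0),
                                          radius = 15, activity = 1.0,
                                          density = 1.0, label = 2L)),
                       background = list(activity = 0.1, density = 1.0,
                                         label = 1L))
  ph <- make_phantom(spec)
  expect_identical(dim(ph$activity$data), dim(ph$density$data))
  expect_identical(dim(ph$activity$data), dim(ph$region_map$labels))
  expect_equal(ph$activity$voxel_size, ph$density$voxel_size)
  labs <- sort(unique(as.vector(ph$region_map$labels)))
  expect_identical(labs, c(1L, 2L))
  expect_true(all(ph$activity$data[ph$region_map$labels == 2L] == 1.0))
  expect_true(all(ph$activity$data[ph$region_map$labels == 1L] == 0.1))
})

test_that("digital sphere volume converges to the analytic volume with voxel size", {
  # voxel-centre digitization error oscillates with the grid alignment at
  # SPECT voxel sizes (up to ~8% at 4.42 mm) and shrinks with refinement
  for (r in c(12, 15, 20, 30)) {
    err <- vapply(c(4.42, 2.21, 1.105), function(h) {
      m <- sphere_mask(r, h, ceiling(2 * (r + 3 * h) / h / 2) * 2)
      abs(sum(m) * h^3 / (4 / 3 * pi * r^3) - 1)
    }, numeric(1))
    expect_lt(err[1], 0.08)
    expect_lt(err[2], 0.04)
    expect_lt(err[3], 0.02)
  }
})

test_that("empty body list yields uniform background volumes", {
  spec <- phantom_spec(c(16, 16, 16), c(4, 4, 4),
                       background = list(activity = 0.2, density = 1.0,
                                         label = 1L))
  ph <- make_phantom(spec)
  expect_true(all(ph$activity$data == 0.2))
  expect_true(all(ph$density$data == 1.0))
  expect_true(all(ph$region_map$labels == 1L))
})

test_that("primitives outside the matrix are rejected and painting order resolves overlaps", {
  expect_error(make_phantom(phantom_spec(c(16, 16, 16), c(4, 4, 4),
    bodies = list(list(shape = "sphere", center = c(30, 0, 0), radius = 10,
                       activity = 1, density = 1, label = 2L)))),
    "outside")
  ph <- make_phantom(phantom_spec(c(32, 32, 32), c(4, 4, 4),
    bodies = list(
      list(shape = "sphere", center = c(0, 0, 0), radius = 20,
           activity = 1, density = 1, label = 2L),
      list(shape = "sphere", center = c(10, 0, 0), radius = 15,
           activity = 2, density = 1, label = 3L))))
  # overlap carries the later label
  expect_true(all(ph$activity$data[ph$region_map$labels == 3L] == 2))
  expect_true(any(ph$region_map$labels == 2L))
})

test_that("NEMA phantom defaults span 1.2 to 113.1 mL with six distinct labels", {
  ph <- make_nema_phantom(0.5, 0.05)
  labs <- sort(unique(as.vector(ph$region_map$labels)))
  expect_identical(labs, 1:8)  # torso 1, spheres 2..7, surrounding air 8
  expect_equal(min(ph$sphere_volumes_ml), 1.2)
  expect_equal(max(ph$sphere_volumes_ml), 113.1)
  # six distinct positive sphere labels, each non-empty
  for (l in 2:7) expect_gt(sum(ph$region_map$labels == l), 0)
  # equal concentrations give a uniform torso; the air region stays cold
  ph2 <- make_nema_phantom(0.3, 0.3)
  inside <- ph2$region_map$labels != 8L
  expect_true(all(ph2$activity$data[inside] == 0.3))
  expect_true(all(ph2$activity$data[!inside] == 0))
})

test_that("Poisson noise has correct moments, determinism and rejects bad input", {
  geom <- small_geometry(n = 4L, n_views = 2L, nz = 4L)
  mean_counts <- 10000
  clean <- projection_set(array(mean_counts, c(4, 4, 2, 1)), geom)
  draws <- vapply(1:1000, function(s)
    add_poisson_noise(clean, seed = s)$counts[1, 1, 1, 1], numeric(1))
  expect_lt(abs(mean(draws) / mean_counts - 1), 0.01)
  expect_lt(abs(var(draws) / mean_counts - 1), 0.05)
  # all-zero in, all-zero out; identical seeds agree
  zero <- projection_set(array(0, c(4, 4, 2, 1)), geom)
  expect_true(all(add_poisson_noise(zero, 1)$counts == 0))
  expect_identical(add_poisson_noise(clean, 7)$counts,
                   add_poisson_noise(clean, 7)$counts)
  bad <- clean; bad$counts[1] <- -1
  expect_error(add_poisson_noise(bad, 1), ">= 0")
  expect_error(add_poisson_noise(clean, NULL), "seed")
})

test_that("bootstrap realizations conserve totals with Poisson-like variance", {
  geom <- small_geometry(n = 4L, n_views = 2L, nz = 4L)
  parent <- projection_set(array(5000, c(4, 4, 2, 1)), geom, is_noisy = TRUE)
  set <- bootstrap_realizations(parent, n_bins = 45, n_realizations = 200,
                                seed = 11)
  expect_equal(set$parent_total_counts, 5000 * 32)
  tot <- vapply(set$realizations, function(p) sum(p$counts), numeric(1))
  expect_lt(abs(mean(tot) / set$parent_total_counts - 1), 0.02)
  px <- vapply(set$realizations, function(p) p$counts[2, 3, 1, 1], numeric(1))
  # Var = N (1 - 1/B), close to the Poisson variance N; a single pixel's
  # sample variance is noisy, the average over pixels is a tight statistic
  expect_lt(abs(var(px) / 5000 - 1), 0.5)
  allv <- apply(vapply(set$realizations, function(p) as.vector(p$counts),
                       numeric(32)), 1, var)
  expect_lt(abs(mean(allv) / 5000 - 1), 0.20)
  # counts are non-negative integers
  expect_true(all(px == round(px)) && all(px >= 0))
  # n_bins = 1 reproduces the parent exactly
  one <- bootstrap_realizations(parent, 1, 3, seed = 2)
  for (p in one$realizations) expect_identical(p$counts, parent$counts)
  frac <- parent; frac$counts[1] <- 0.5
  expect_error(bootstrap_realizations(frac, 4, 2, seed = 1), "integer")
})

test_that("scaling expected counts by k reduces relative noise of region means by ~1/sqrt(k)", {
  ph <- two_region_phantom()
  geom <- acquisition_geometry(n_views = 10, orbit_radius_mm = 200,
                               pixel_size_mm = c(4.42, 4.42),
                               detector_shape = c(32L, 16L),
                               time_per_view_s = 10)
  truth <- source_model(ph$activity, ph$region_map, c(2, 2, 1), "rv")
  clean <- forward_project(truth, NULL, geom, NULL, NULL, calibration = 2)
  rel_sd <- function(scale_k) {
    cl <- clean; cl$counts <- cl$counts * scale_k
    ms <- vapply(1:40, function(s) {
      n <- add_poisson_noise(cl, seed = 1000 + s)
      mean(n$counts[10:20, 6:10, 1, 1])
    }, numeric(1))
    sd(ms) / mean(ms)
  }
  r1 <- rel_sd(1); r4 <- rel_sd(4)
  expect_lt(abs((r1 / r4) / 2 - 1), 0.25)
})

test_that("phantom specs round-trip through JSON and YAML", {
  spec <- phantom_spec(c(16, 16, 8), c(4, 4, 8), bodies = list(
    list(shape = "box", center = c(0, 0, 0), size = c(20, 20, 16),
         activity = 0.5, density = 1.0, label = 2L)),
    background = list(activity = 0.1, density = 1.0, label = 1L))
  for (ext in c("json", "yaml")) {
    path <- file.path(tempdir(), paste0("spec.", ext))
    write_phantom_spec(spec, path)
    back <- read_phantom_spec(path)
    ph1 <- make_phantom(spec); ph2 <- make_phantom(back)
    expect_identical(ph1$activity$data, ph2$activity$data)
    expect_identical(ph1$region_map$labels, ph2$region_map$labels)
  }
})
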