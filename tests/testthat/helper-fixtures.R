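# Shared fixture builders for the test suite.  Everything is generated in
# code; sizes are kept small except where a test needs the full emulated
# matrix scale.

small_geometry <- function(n = 32L, n_views = 6L, nz = n, time = 10,
                           orbit = 200, beds = 0) {
  acquisition_geometry(n_views = n_views, orbit_radius_mm = orbit,
                       pixel_size_mm = c(4.42, 4.42),
                       detector_shape = c(n, nz), time_per_view_s = time,
                       bed_axial_offsets_mm = beds)
}

# digital sphere mask on an n^3 grid (voxel-centre test)
sphere_mask <- function(radius_mm, voxel_size, n) {
  vs <- rep_len(voxel_size, 3L)
  n <- rep_len(n, 3L)
  co <- lapply(1:3, function(a) (seq_len(n[a]) - (n[a] + 1) / 2) * vs[a])
  outer(outer(co[[1]]^2, co[[2]]^2, "+"), co[[3]]^2, "+") <= radius_mm^2
}

# random non-negative source supported on the inscribed transaxial disc
disc_source <- function(n, vs = c(4.42, 4.42, 4.42), margin = 3) {
  co <- (seq_len(n) - (n + 1) / 2)
  m <- outer(outer(co^2, co^2, "+"), co * 0, "+") <= (n / 2 - margin)^2
  volume_grid(array(stats::runif(n^3), c(n, n, n)) * m, vs)
}

# small two-region phantom at internal resolution for reconstruction tests
two_region_phantom <- function(ni = c(64, 64, 16), fac = c(2, 2, 1),
                               vs_i = c(2.21, 2.21, 4.42)) {
  spec <- phantom_spec(ni, vs_i, bodies = list(
    list(shape = "sphere", center = c(-20, 0, 0), radius = 18,
         activity = 1.0, density = 1.0, label = 2L),
    list(shape = "ellipsoid", center = c(30, 10, 0), semiaxes = c(14, 20, 20),
         activity = 0.5, density = 1.05, label = 3L)),
    background = list(activity = 0.1, density = 1.0, label = 1L))
  make_phantom(spec)
}
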