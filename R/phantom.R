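#' Digital phantom specification
#'
#' Describes a synthetic phantom as a list of geometric primitives painted
#' in order into a uniform background.  Each body carries an activity
#' concentration (MBq/mL), a mass density (g/cm3) and a positive integer
#' region label; bodies listed later overwrite earlier ones voxel-wise.
#' Voxel membership uses the voxel-centre test (no anti-aliasing) so that
#' the painted activity map agrees exactly with the painted region map, the
#' assumption underlying regional-voxel estimation.
#'
#' @param matrix_shape integer triple.
#' @param voxel_size mm triple.
#' @param bodies list of primitives, each a list with fields `shape`
#'   (`"sphere"`, `"ellipsoid"`, `"cylinder"`, `"box"`), `center` (mm,
#'   relative to the volume centre), size fields (`radius`; `semiaxes`;
#'   `radius` + `length` + optional `axis` (1-3, default 3); `size`),
#'   `activity` (MBq/mL), `density` (g/cm3), `label` (positive int).
#' @param background list with `activity`, `density`, `label`.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(matrix_shape, voxel_size, bodies = list(),
                         background = list(activity = 0, density = 0,
                                           label = 1L)) {
  matrix_shape <- as.integer(rep_len(matrix_shape, 3L))
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(matrix_shape < 1L) || any(voxel_size <= 0))
    stop("invalid matrix shape or voxel size")
  labs <- integer(0)
  for (b in bodies) {
    if (is.null(b$shape) || !b$shape %in% c("sphere", "ellipsoid", "cylinder", "box"))
      stop("unknown primitive shape: ", b$shape)
    if (b$activity < 0 || b$density < 0)
      stop("activity concentrations and densities must be >= 0")
    lab <- as.integer(b$label)
    if (lab <= 0L) stop("body labels must be positive integers")
    if (lab %in% labs) stop("duplicate body label ", lab)
    labs <- c(labs, lab)
  }
  if (background$activity < 0 || background$density < 0)
    stop("background activity and density must be >= 0")
  structure(list(matrix_shape = matrix_shape, voxel_size = voxel_size,
                 bodies = bodies, background = background),
            class = "phantom_spec")
}

body_half_extent <- function(b) {
  switch(b$shape,
         sphere = rep(b$radius, 3),
         ellipsoid = rep_len(b$semiaxes, 3L),
         cylinder = {
           ax <- if (is.null(b$axis)) 3L else as.integer(b$axis)
           h <- rep(b$radius, 3); h[ax] <- b$length / 2; h
         },
         box = rep_len(b$size, 3L) / 2)
}

body_mask <- function(b, cx, cy, cz) {
  dx <- cx - b$center[1]; dy <- cy - b$center[2]; dz <- cz - b$center[3]
  switch(b$shape,
         sphere = outer(outer(dx^2, dy^2, "+"), dz^2, "+") <= b$radius^2,
         ellipsoid = {
           s <- rep_len(b$semiaxes, 3L)
           outer(outer((dx / s[1])^2, (dy / s[2])^2, "+"),
                 (dz / s[3])^2, "+") <= 1
         },
         cylinder = {
           ax <- if (is.null(b$axis)) 3L else as.integer(b$axis)
           d <- list(dx, dy, dz)
           tr <- setdiff(1:3, ax)
           r2 <- outer(outer(if (1 %in% tr) d[[1]]^2 else d[[1]] * 0,
                             if (2 %in% tr) d[[2]]^2 else d[[2]] * 0, "+"),
                       if (3 %in% tr) d[[3]]^2 else d[[3]] * 0, "+")
           ok_ax <- abs(d[[ax]]) <= b$length / 2
           ax_arr <- switch(ax,
                            outer(outer(ok_ax, dy * 0 + 1, "*"), dz * 0 + 1, "*"),
                            outer(outer(dx * 0 + 1, ok_ax, "*"), dz * 0 + 1, "*"),
                            outer(outer(dx * 0 + 1, dy * 0 + 1, "*"), ok_ax, "*"))
           (r2 <= b$radius^2) & (ax_arr > 0)
         },
         box = {
           h <- rep_len(b$size, 3L) / 2
           outer(outer(abs(dx) <= h[1], abs(dy) <= h[2], "&"),
                 abs(dz) <= h[3], "&")
         })
}

#' Rasterize a phantom specification
#'
#' Produces three co-registered volumes: activity concentration (MBq/mL),
#' density (g/cm3), and an integer region map.  A primitive whose extent
#' does not fit inside the matrix is rejected.
#'
#' @param spec a [phantom_spec].
#' @param unlabeled_slices passed to the resulting [region_map].
#' @return list with `activity`, `density` ([volume_grid]) and `region_map`
#'   ([region_map]).
#' @export
make_phantom <- function(spec, unlabeled_slices = c(0L, 0L)) {
  stopifnot(inherits(spec, "phantom_spec"))
  shp <- spec$matrix_shape; vs <- spec$voxel_size
  co <- grid_coords(shp, vs)
  half_fov <- shp * vs / 2
  act <- array(spec$background$activity, dim = shp)
  den <- array(spec$background$density, dim = shp)
  lab <- array(as.integer(spec$background$label), dim = shp)
  for (b in spec$bodies) {
    he <- body_half_extent(b)
    if (any(abs(b$center) + he > half_fov + 1e-9))
      stop("primitive with label ", b$label, " extends outside the matrix")
    m <- body_mask(b, co[[1]], co[[2]], co[[3]])
    act[m] <- b$activity
    den[m] <- b$density
    lab[m] <- as.integer(b$label)
  }
  list(activity = volume_grid(act, vs),
       density = volume_grid(den, vs),
       region_map = region_map(lab, vs,
                               background_label = spec$background$label,
                               unlabeled_slices = unlabeled_slices))
}

#' NEMA-style six-sphere body phantom
#'
#' A torso-shaped (elliptic cylinder) water background containing six hot
#' spheres of configurable volumes arranged on a ring in the central
#' transversal plane.  The default volume set spans 1.2 mL to 113.1 mL.
#' Each sphere receives a distinct region label (2..7); the torso background
#' is label 1 and the surrounding air is its own region (label 8, named
#' "air") so that the phantom's truth is region-wise constant everywhere
#' -- air is a nuisance region, not an evaluated structure.
#'
#' @param sphere_concentration activity concentration in the spheres
#'   (MBq/mL).
#' @param background_concentration activity concentration in the torso
#'   background (MBq/mL).
#' @param sphere_volumes_ml the six sphere volumes (mL).
#' @param matrix_shape,voxel_size grid of the phantom.
#' @param torso_semiaxes_mm in-plane semi-axes of the torso.
#' @param torso_length_mm axial extent of the torso.
#' @param ring_radius_mm radius of the sphere-centre ring.
#' @param density body density in g/cm3 (water).
#' @param unlabeled_slices passed to the region map.
#' @return as [make_phantom()].
#' @export
make_nema_phantom <- function(sphere_concentration, background_concentration,
                              sphere_volumes_ml = c(1.2, 2.6, 5.6, 11.5, 26.5, 113.1),
                              matrix_shape = c(64, 64, 64),
                              voxel_size = c(4.42, 4.42, 4.42),
                              torso_semiaxes_mm = c(120, 90),
                              torso_length_mm = 210,
                              ring_radius_mm = 57.2,
                              density = 1.0,
                              unlabeled_slices = c(0L, 0L)) {
  if (sphere_concentration < 0 || background_concentration < 0)
    stop("concentrations must be >= 0")
  if (length(sphere_volumes_ml) != 6L) stop("exactly six sphere volumes expected")
  radii <- (3 * sphere_volumes_ml * 1000 / (4 * pi))^(1 / 3)  # mm
  ang <- (seq_len(6) - 1) * 60 * pi / 180
  bodies <- list()
  for (i in seq_len(6)) {
    bodies[[i]] <- list(shape = "sphere",
                        center = c(ring_radius_mm * cos(ang[i]),
                                   ring_radius_mm * sin(ang[i]), 0),
                        radius = radii[i],
                        activity = sphere_concentration, density = density,
                        label = i + 1L)
  }
  shp <- as.integer(rep_len(matrix_shape, 3L))
  vs <- rep_len(as.numeric(voxel_size), 3L)
  co <- grid_coords(shp, vs)
  torso <- outer(outer((co[[1]] / torso_semiaxes_mm[1])^2,
                       (co[[2]] / torso_semiaxes_mm[2])^2, "+"),
                 co[[3]] * 0, "+") <= 1
  torso <- torso & outer(outer(co[[1]] * 0, co[[2]] * 0, "+"),
                         abs(co[[3]]) <= torso_length_mm / 2, "+") > 0
  act <- array(0, dim = shp); den <- array(0, dim = shp)
  lab <- array(8L, dim = shp)
  act[torso] <- background_concentration
  den[torso] <- density
  lab[torso] <- 1L
  for (b in bodies) {
    m <- body_mask(b, co[[1]], co[[2]], co[[3]])
    act[m] <- b$activity; den[m] <- b$density; lab[m] <- b$label
  }
  nm <- c("background", paste0("sphere_", signif(sphere_volumes_ml, 4), "mL"),
          "air")
  names(nm) <- as.character(1:8)
  list(activity = volume_grid(act, vs),
       density = volume_grid(den, vs),
       region_map = region_map(lab, vs, label_names = nm,
                               background_label = 1L,
                               unlabeled_slices = unlabeled_slices),
       sphere_volumes_ml = sphere_volumes_ml,
       sphere_radii_mm = radii)
}

#' Organ-scale abdominal phantom
#'
#' A simplified abdomen for organ-level quantification experiments: two
#' kidney-like ellipsoids (about 150 mL each), a spleen-like ellipsoid
#' (about 200 mL) and a small tumor sphere inside a water torso.  Default
#' concentrations mimic a 177Lu radionuclide-therapy distribution with
#' high organ-to-background contrast.
#'
#' @param kidney_concentration,spleen_concentration,tumor_concentration,background_concentration
#'   activity concentrations in MBq/mL.
#' @param tumor_radius_mm radius of the tumor sphere.
#' @param matrix_shape,voxel_size grid of the phantom.
#' @param unlabeled_slices passed to the region map.
#' @return as [make_phantom()]; labels: background 1, left kidney 2, right
#'   kidney 3, spleen 4, tumor 5, surrounding air 6 (a nuisance region, so
#'   the truth is region-wise constant over the whole field of view).
#' @export
make_organ_phantom <- function(kidney_concentration = 0.3,
                               spleen_concentration = 0.2,
                               tumor_concentration = 1.0,
                               background_concentration = 0.02,
                               tumor_radius_mm = 12.5,
                               matrix_shape = c(64, 64, 64),
                               voxel_size = c(4.42, 4.42, 4.42),
                               unlabeled_slices = c(0L, 0L)) {
  shp <- as.integer(rep_len(matrix_shape, 3L))
  vs <- rep_len(as.numeric(voxel_size), 3L)
  co <- grid_coords(shp, vs)
  torso <- outer(outer((co[[1]] / 125)^2, (co[[2]] / 95)^2, "+"),
                 co[[3]] * 0, "+") <= 1
  torso <- torso & outer(outer(co[[1]] * 0, co[[2]] * 0, "+"),
                         abs(co[[3]]) <= 110, "+") > 0
  act <- array(0, shp); den <- array(0, shp); lab <- array(6L, shp)
  act[torso] <- background_concentration
  den[torso] <- 1.0
  lab[torso] <- 1L
  bodies <- list(
    list(shape = "ellipsoid", center = c(-55, -30, 0),
         semiaxes = c(25, 35, 40),
         activity = kidney_concentration, density = 1.05, label = 2L),
    list(shape = "ellipsoid", center = c(55, -30, 0),
         semiaxes = c(25, 35, 40),
         activity = kidney_concentration, density = 1.05, label = 3L),
    list(shape = "ellipsoid", center = c(55, 25, 25),
         semiaxes = c(32, 38, 40),
         activity = spleen_concentration, density = 1.05, label = 4L),
    list(shape = "sphere", center = c(-30, 45, -40),
         radius = tumor_radius_mm,
         activity = tumor_concentration, density = 1.05, label = 5L))
  for (b in bodies) {
    m <- body_mask(b, co[[1]], co[[2]], co[[3]])
    act[m] <- b$activity; den[m] <- b$density; lab[m] <- b$label
  }
  nm <- c("background", "kidney_left", "kidney_right", "spleen", "tumor",
          "air")
  names(nm) <- as.character(1:6)
  list(activity = volume_grid(act, vs),
       density = volume_grid(den, vs),
       region_map = region_map(lab, vs, label_names = nm,
                               background_label = 1L,
                               unlabeled_slices = unlabeled_slices))
}

#' Add Poisson counting noise to expected-count projections
#'
#' Each detector pixel is drawn independently from a Poisson distribution
#' with the input value as mean.  Deterministic for a fixed seed.
#'
#' @param projections a [projection_set] of expected counts (>= 0, finite).
#' @param seed integer seed (required).
#' @return a [projection_set] of integer counts with `is_noisy = TRUE`.
#' @export
add_poisson_noise <- function(projections, seed) {
  stopifnot(inherits(projections, "projection_set"))
  x <- projections$counts
  if (any(!is.finite(x)) || any(x < 0))
    stop("expected counts must be finite and >= 0")
  noisy <- with_seed(seed, rpois(length(x), as.vector(x)))
  projections$counts <- array(as.numeric(noisy), dim = dim(x))
  projections$is_noisy <- TRUE
  projections
}

#' List-mode-style bootstrap noise realizations
#'
#' Emulates the bootstrap used with list-mode acquisitions: each pixel's
#' parent count is multinomially split into `n_bins` time bins, and every
#' realization draws `n_bins` bins with replacement (one shared draw per
#' realization, as resampled time bins are global) and sums them.  The
#' expected total count of a realization equals the parent total, and the
#' per-pixel variance across realizations is `N * (1 - 1/n_bins)`,
#' Poisson-like for large `n_bins`.
#'
#' @param parent a [projection_set] with integer counts.
#' @param n_bins number of time bins (>= 1); e.g. one-second bins.
#' @param n_realizations number of realizations to generate.
#' @param seed integer seed (required).
#' @return object of class `noise_realization_set`: list with
#'   `realizations` (list of [projection_set]), `seed`,
#'   `parent_total_counts`.
#' @export
bootstrap_realizations <- function(parent, n_bins, n_realizations, seed) {
  stopifnot(inherits(parent, "projection_set"))
  x <- as.vector(parent$counts)
  if (any(abs(x - round(x)) > 1e-9) || any(x < 0))
    stop("parent counts must be non-negative integers")
  x <- round(x)
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop("n_bins must be >= 1")
  out <- with_seed(seed, {
    # sequential binomial thinning == multinomial split per pixel
    bins <- matrix(0, length(x), n_bins)
    remaining <- x
    if (n_bins > 1L) {
      for (b in seq_len(n_bins - 1L)) {
        bins[, b] <- rbinom(length(x), remaining, 1 / (n_bins - b + 1L))
        remaining <- remaining - bins[, b]
      }
    }
    bins[, n_bins] <- remaining
    lapply(seq_len(n_realizations), function(r) {
      draw <- sample.int(n_bins, n_bins, replace = TRUE)
      cnt <- tabulate(draw, nbins = n_bins)
      y <- as.vector(bins %*% cnt)
      ps <- parent
      ps$counts <- array(as.numeric(y), dim = dim(parent$counts))
      ps$is_noisy <- TRUE
      ps
    })
  })
  structure(list(realizations = out, seed = as.integer(seed),
                 parent_total_counts = sum(x)),
            class = "noise_realization_set")
}

#' Read / write a phantom specification as JSON or YAML
#'
#' @param spec a [phantom_spec].
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return `read_phantom_spec` returns a [phantom_spec].
#' @export
write_phantom_spec <- function(spec, path) {
  obj <- unclass(spec)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(obj, path)
  else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = FALSE)
  bodies <- lapply(obj$bodies, function(b) lapply(b, unlist))
  phantom_spec(unlist(obj$matrix_shape), unlist(obj$voxel_size),
               bodies = bodies, background = lapply(obj$background, unlist))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
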