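#' SPECT acquisition geometry
#'
#' Describes a step-and-shoot acquisition: view angles over the orbit, the
#' orbit radius per view (collimator face to rotation axis), detector pixel
#' grid, acquisition time per view, and the axial offsets of the bed
#' positions (a single bed is `bed_axial_offsets = 0`).  An optional
#' `detector_mask` marks detector pixels as valid; pixels outside the mask
#' are excluded from projections and from the OS-EM update ratios,
#' representing a physical detector smaller than the projection matrix.
#'
#' The default parameters mirror a common 177Lu protocol: 60 views over
#' 360 degrees, 128 x 128 projections with 4.42 mm pixels, 45 s per view.
#'
#' @param n_views number of views.
#' @param angles view angles in degrees, in `[0, 360)`; default equally
#'   spaced over 360 degrees.
#' @param orbit_radius_mm orbit radius per view (scalar recycled).
#' @param pixel_size_mm detector pixel size (length 2).
#' @param detector_shape detector pixel grid (length 2: transaxial, axial).
#' @param time_per_view_s acquisition time per view in seconds.
#' @param bed_axial_offsets_mm axial offset per bed position.
#' @param detector_mask optional logical/0-1 matrix of shape
#'   `detector_shape`.
#' @return object of class `acquisition_geometry`.
#' @export
acquisition_geometry <- function(n_views = 60L,
                                 angles = NULL,
                                 orbit_radius_mm = 250,
                                 pixel_size_mm = c(4.42, 4.42),
                                 detector_shape = c(128L, 128L),
                                 time_per_view_s = 45,
                                 bed_axial_offsets_mm = 0,
                                 detector_mask = NULL) {
  n_views <- as.integer(n_views)
  if (is.null(angles)) angles <- (seq_len(n_views) - 1) * 360 / n_views
  if (length(angles) != n_views) stop("length(angles) != n_views")
  if (any(angles < 0 | angles >= 360))
    stop("angles must lie in [0, 360)")
  orbit_radius_mm <- rep_len(as.numeric(orbit_radius_mm), n_views)
  if (any(orbit_radius_mm <= 0)) stop("orbit radii must be > 0")
  if (time_per_view_s <= 0) stop("time_per_view_s must be > 0")
  detector_shape <- as.integer(rep_len(detector_shape, 2L))
  if (!is.null(detector_mask)) {
    detector_mask <- (as.matrix(detector_mask) != 0)
    if (!identical(dim(detector_mask), detector_shape))
      stop("detector_mask does not match detector_shape")
  }
  structure(list(n_views = n_views, angles = as.numeric(angles),
                 orbit_radius_mm = orbit_radius_mm,
                 pixel_size_mm = rep_len(as.numeric(pixel_size_mm), 2L),
                 detector_shape = detector_shape,
                 time_per_view_s = as.numeric(time_per_view_s),
                 bed_axial_offsets_mm = as.numeric(bed_axial_offsets_mm),
                 detector_mask = detector_mask),
            class = "acquisition_geometry")
}

n_beds <- function(geom) length(geom$bed_axial_offsets_mm)

#' @export
print.acquisition_geometry <- function(x, ...) {
  cat(sprintf("<acquisition_geometry> %d views, %dx%d pixels of %gx%g mm, %g s/view, %d bed(s)\n",
              x$n_views, x$detector_shape[1], x$detector_shape[2],
              x$pixel_size_mm[1], x$pixel_size_mm[2], x$time_per_view_s,
              n_beds(x)))
  invisible(x)
}

#' Projection data container
#'
#' Per-view count images plus their acquisition geometry.  `counts` is a 4D
#' array `[u, v, view, bed]` of expected counts (noise free) or integer
#' observed counts.
#'
#' @param counts 3D `[u, v, view]` (single bed) or 4D `[u, v, view, bed]`
#'   array, all values >= 0.
#' @param geometry an [acquisition_geometry].
#' @param is_noisy whether counts are an observed (integer) realization.
#' @return object of class `projection_set`.
#' @export
projection_set <- function(counts, geometry, is_noisy = FALSE) {
  counts <- as.array(counts)
  if (length(dim(counts)) == 3L) dim(counts) <- c(dim(counts), 1L)
  if (length(dim(counts)) != 4L) stop("'counts' must be 3D or 4D")
  expect <- c(geometry$detector_shape, geometry$n_views, n_beds(geometry))
  if (!identical(dim(counts), as.integer(expect)))
    stop("counts shape ", paste(dim(counts), collapse = "x"),
         " inconsistent with geometry ", paste(expect, collapse = "x"))
  if (any(counts < 0)) stop("counts must be >= 0")
  structure(list(counts = counts, geometry = geometry,
                 is_noisy = isTRUE(is_noisy)),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  cat(sprintf("<projection_set> %s counts (%s), total %.4g\n",
              paste(dim(x$counts), collapse = "x"),
              if (x$is_noisy) "noisy" else "expected", sum(x$counts)))
  invisible(x)
}

total_counts <- function(ps) sum(ps$counts)

#' Serialize projections as multi-frame NIfTI + geometry sidecar
#'
#' Counts are written as a float64 NIfTI with the view index on the 4th
#' axis (beds concatenated along views), and the geometry as a JSON
#' sidecar; the round trip is bit exact.
#'
#' @param ps a [projection_set].
#' @param path base path; writes `<path>.nii.gz` and `<path>.json`.
#' @return `read_projections` returns a [projection_set].
#' @export
write_projections <- function(ps, path) {
  d <- dim(ps$counts)
  arr <- ps$counts
  dim(arr) <- c(d[1], d[2], 1L, d[3] * d[4])  # u, v, dummy, view*bed
  img <- RNifti::asNifti(arr)
  aff <- diag(4)
  diag(aff)[1:2] <- ps$geometry$pixel_size_mm
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, paste0(path, ".nii.gz"), datatype = "double")
  g <- ps$geometry
  meta <- list(n_views = g$n_views, angles = g$angles,
               orbit_radius_mm = g$orbit_radius_mm,
               pixel_size_mm = g$pixel_size_mm,
               detector_shape = g$detector_shape,
               time_per_view_s = g$time_per_view_s,
               bed_axial_offsets_mm = g$bed_axial_offsets_mm,
               detector_mask = if (is.null(g$detector_mask)) NULL
                               else as.integer(g$detector_mask),
               is_noisy = ps$is_noisy)
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' @rdname write_projections
#' @export
read_projections <- function(path) {
  img <- RNifti::readNifti(paste0(path, ".nii.gz"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  mask <- NULL
  if (!is.null(meta$detector_mask) && length(meta$detector_mask))
    mask <- matrix(meta$detector_mask != 0, meta$detector_shape[1],
                   meta$detector_shape[2])
  geom <- acquisition_geometry(n_views = meta$n_views, angles = meta$angles,
                               orbit_radius_mm = meta$orbit_radius_mm,
                               pixel_size_mm = meta$pixel_size_mm,
                               detector_shape = meta$detector_shape,
                               time_per_view_s = meta$time_per_view_s,
                               bed_axial_offsets_mm = meta$bed_axial_offsets_mm,
                               detector_mask = mask)
  arr <- array(as.numeric(img),
               dim = c(meta$detector_shape, meta$n_views,
                       length(meta$bed_axial_offsets_mm)))
  projection_set(arr, geom, is_noisy = isTRUE(meta$is_noisy))
}

#' Read / write an acquisition geometry as YAML or JSON
#' @param geometry an [acquisition_geometry].
#' @param path file path (`.yaml`, `.yml` or `.json`).
#' @return `read_geometry` returns an [acquisition_geometry].
#' @export
write_geometry <- function(geometry, path) {
  g <- unclass(geometry)
  g$detector_mask <- if (is.null(g$detector_mask)) NULL
                     else as.integer(g$detector_mask)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(g, path)
  else jsonlite::write_json(g, path, digits = NA)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  g <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = TRUE)
  mask <- NULL
  if (!is.null(g$detector_mask) && length(g$detector_mask))
    mask <- matrix(unlist(g$detector_mask) != 0, g$detector_shape[1],
                   g$detector_shape[2])
  acquisition_geometry(n_views = g$n_views, angles = unlist(g$angles),
                       orbit_radius_mm = unlist(g$orbit_radius_mm),
                       pixel_size_mm = unlist(g$pixel_size_mm),
                       detector_shape = unlist(g$detector_shape),
                       time_per_view_s = g$time_per_view_s,
                       bed_axial_offsets_mm = unlist(g$bed_axial_offsets_mm),
                       detector_mask = mask)
}
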