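#' Region map: integer-labelled geometry for regional voxels
#'
#' A region map assigns every internal-grid voxel to an anatomical region
#' (positive integer label), to the background region, or to label 0
#' ("unlabelled").  Label 0 voxels are not part of any region and are
#' updated voxel-wise (at the emulated voxel size) during reconstruction.
#' The first/last `unlabeled_slices` transversal slices are conventionally
#' left at 0 to avoid interference from zero-count projection rows where the
#' physical detector is smaller than the projection matrix.
#'
#' @param labels integer 3D array of region labels (>= 0).
#' @param voxel_size voxel size in mm (length 3).
#' @param label_names optional named character vector, names = labels.
#' @param background_label integer label of the background region.
#' @param unlabeled_slices integer pair: number of first / last transversal
#'   (z) slices forced to label 0.
#' @return an object of class `region_map`.
#' @export
region_map <- function(labels, voxel_size, label_names = NULL,
                       background_label = 1L, unlabeled_slices = c(0L, 0L)) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L) stop("'labels' must be a 3D array")
  storage.mode(labels) <- "integer"
  if (any(labels < 0L)) stop("region labels must be >= 0")
  unlabeled_slices <- as.integer(rep_len(unlabeled_slices, 2L))
  nz <- dim(labels)[3]
  if (sum(unlabeled_slices) > nz)
    stop("unlabeled slices exceed the number of transversal slices")
  if (unlabeled_slices[1] > 0L) labels[, , seq_len(unlabeled_slices[1])] <- 0L
  if (unlabeled_slices[2] > 0L)
    labels[, , nz - seq_len(unlabeled_slices[2]) + 1L] <- 0L
  structure(list(labels = labels,
                 voxel_size = rep_len(as.numeric(voxel_size), 3L),
                 label_names = label_names,
                 background_label = as.integer(background_label),
                 unlabeled_slices = unlabeled_slices),
            class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  labs <- sort(unique(as.vector(x$labels)))
  cat(sprintf("<region_map> %s voxels of %s mm; labels {%s}; background %d; unlabeled slices %d/%d\n",
              paste(dim(x$labels), collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x"),
              paste(labs, collapse = ","), x$background_label,
              x$unlabeled_slices[1], x$unlabeled_slices[2]))
  invisible(x)
}

#' Build a region map from VOI masks
#'
#' Paints the supplied binary masks in order (later masks overwrite earlier
#' ones where they overlap), assigns `background_label` to every voxel not
#' covered by any mask, and finally forces the first/last `unlabeled_slices`
#' transversal slices to label 0.  The default of 25 unlabelled slices at
#' each end matches the convention used with 128-slice acquisitions where
#' the camera's axial field of view is smaller than the matrix.
#'
#' @param voi_masks list of `list(label = <positive int>, mask = <logical or
#'   0/1 array>)`, all on the same grid.
#' @param voxel_size voxel size in mm.
#' @param shape matrix shape, required when `voi_masks` is empty.
#' @param background_label label for uncovered voxels.
#' @param unlabeled_slices first/last slices left unlabelled.
#' @param label_names optional named character vector.
#' @return a [region_map].
#' @export
build_region_map <- function(voi_masks, voxel_size, shape = NULL,
                             background_label = 1L,
                             unlabeled_slices = c(25L, 25L),
                             label_names = NULL) {
  if (length(voi_masks) == 0L) {
    if (is.null(shape)) stop("'shape' is required when no masks are given")
    labels <- array(as.integer(background_label), dim = shape)
  } else {
    shp <- dim(as.array(voi_masks[[1]]$mask))
    labels <- array(as.integer(background_label), dim = shp)
    lab_seen <- integer(0)
    for (vm in voi_masks) {
      m <- as.array(vm$mask)
      if (!identical(dim(m), shp))
        stop("VOI mask grids do not match")
      lab <- as.integer(vm$label)
      if (lab <= 0L) stop("VOI labels must be positive")
      if (lab %in% lab_seen) stop("duplicate VOI label ", lab)
      lab_seen <- c(lab_seen, lab)
      labels[m != 0] <- lab
    }
  }
  region_map(labels, voxel_size, label_names = label_names,
             background_label = background_label,
             unlabeled_slices = unlabeled_slices)
}

#' Average a volume within each labelled region
#'
#' Computes the arithmetic mean of `volume` over the member voxels of every
#' positive label in `region_map`, and a broadcast volume in which each
#' voxel carries its region's mean.  Label-0 voxels pass through unchanged.
#' This is the region-averaging step applied to back-projections in
#' regional-voxel OS-EM.
#'
#' @param volume a [volume_grid] (or array) co-registered with `region_map`.
#' @param map a [region_map].
#' @return list with `means` (named numeric vector, names = labels),
#'   `counts` (member voxels per label) and `broadcast` (same class as
#'   `volume`).
#' @export
region_average <- function(volume, map) {
  is_vg <- inherits(volume, "volume_grid")
  arr <- if (is_vg) volume$data else as.array(volume)
  if (!identical(dim(arr), dim(map$labels)))
    stop("volume and region map grids do not match")
  lab <- as.vector(map$labels)
  sel <- lab > 0L
  labs <- sort(unique(lab[sel]))
  sums <- rowsum(as.vector(arr)[sel], lab[sel], reorder = TRUE)
  cnts <- rowsum(rep(1, sum(sel)), lab[sel], reorder = TRUE)
  if (any(cnts == 0)) stop("empty region(s): ",
                           paste(labs[cnts == 0], collapse = ", "))
  means <- as.vector(sums) / as.vector(cnts)
  names(means) <- labs
  out <- as.vector(arr)
  out[sel] <- means[match(lab[sel], labs)]
  dim(out) <- dim(arr)
  broadcast <- if (is_vg) volume_grid(out, volume$voxel_size, volume$origin)
               else out
  cn <- as.vector(cnts); names(cn) <- labs
  list(means = means, counts = cn, broadcast = broadcast)
}

#' Serialize a region map as NIfTI + JSON sidecar
#'
#' @param map a [region_map].
#' @param path base path; writes `<path>.nii.gz` and `<path>.json`.
#' @return `read_region_map` returns a [region_map].
#' @export
write_region_map <- function(map, path) {
  write_volume(volume_grid(map$labels + 0, map$voxel_size), paste0(path, ".nii.gz"))
  meta <- list(background_label = map$background_label,
               unlabeled_slices = map$unlabeled_slices,
               label_names = as.list(map$label_names))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_region_map
#' @export
read_region_map <- function(path) {
  vol <- read_volume(paste0(path, ".nii.gz"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ln <- if (length(meta$label_names)) unlist(meta$label_names) else NULL
  region_map(round(vol$data), vol$voxel_size, label_names = ln,
             background_label = meta$background_label,
             unlabeled_slices = meta$unlabeled_slices)
}
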