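#' Source model: cuboid voxels, regional voxels, or a mixture
#'
#' The source distribution is stored on a fine internal grid (the grid of
#' the region map, e.g. 1.105 x 1.105 x 4.42 mm3) but behaves toward the
#' projector as an image at a coarser emulated voxel size, an exact integer
#' multiple of the internal size (default factor 4 x 4 x 1, i.e. emulated
#' 4.42 mm cubes).  Down-sampling averages, up-sampling partitions, so
#' total activity is conserved in both directions.
#'
#' Modes:
#' * `"cuv"`: no region map; a conventional voxel image at the emulated
#'   size (factor may still be > 1 to allow fine-grid analysis).
#' * `"rv"`: a region map labels the internal grid; the reconstruction
#'   estimates one concentration per labelled region.  Label-0 voxels
#'   (e.g. unlabelled edge slices) are updated voxel-wise at the emulated
#'   size, which mirrors partitioning unlabelled space into cuboid regions
#'   of the emulated size.
#'
#' @param internal a [volume_grid] of activity concentration at internal
#'   resolution, all values >= 0.
#' @param region_map a [region_map] on the same grid, or `NULL` for pure
#'   cuboid voxels.
#' @param emulated_factor integer triple; internal shape must divide.
#' @param mode `"cuv"` or `"rv"`; defaults to `"rv"` when a region map is
#'   present.
#' @return object of class `source_model`.
#' @export
source_model <- function(internal, region_map = NULL,
                         emulated_factor = c(1L, 1L, 1L), mode = NULL) {
  stopifnot(inherits(internal, "volume_grid"))
  if (any(internal$data < 0)) stop("concentrations must be >= 0")
  emulated_factor <- as.integer(rep_len(emulated_factor, 3L))
  if (any(dim(internal$data) %% emulated_factor != 0L))
    stop("internal shape must be divisible by the emulated factor")
  if (!is.null(region_map)) {
    stopifnot(inherits(region_map, "region_map"))
    if (!identical(dim(region_map$labels), dim(internal$data)))
      stop("region map and internal grid do not match")
  }
  if (is.null(mode)) mode <- if (is.null(region_map)) "cuv" else "rv"
  if (mode == "rv" && is.null(region_map))
    stop("mode 'rv' requires a region map")
  structure(list(internal = internal, region_map = region_map,
                 emulated_factor = emulated_factor, mode = mode),
            class = "source_model")
}

#' @export
print.source_model <- function(x, ...) {
  cat(sprintf("<source_model> mode %s, internal %s @ %s mm, emulated factor %s\n",
              x$mode, paste(dim(x$internal$data), collapse = "x"),
              paste(signif(x$internal$voxel_size, 4), collapse = "x"),
              paste(x$emulated_factor, collapse = "x")))
  invisible(x)
}

#' The emulated-grid image the projector sees
#' @param source a [source_model].
#' @return a [volume_grid] at the emulated voxel size.
#' @export
emulated_volume <- function(source) {
  downsample_to_emulated(source$internal, source$emulated_factor)
}

# Replace the internal representation from an emulated-grid image.
set_from_emulated <- function(source, emulated) {
  source$internal <- upsample_to_internal(emulated, source$emulated_factor)
  source
}

#' Read out regional concentration estimates
#'
#' One row per labelled region: label, name, volume (member voxel count
#' times internal voxel volume) and mean concentration.  Only meaningful
#' for regional-voxel models; for cuboid voxels use VOI means instead.
#'
#' @param source a [source_model] in `"rv"` mode.
#' @param iteration optional iteration count to record.
#' @return `data.frame` with columns `label`, `name`, `volume_ml`,
#'   `concentration`, `iteration`.
#' @export
extract_estimates <- function(source, iteration = NA_integer_) {
  if (source$mode != "rv" || is.null(source$region_map))
    stop("extract_estimates requires a regional-voxel source model")
  ra <- region_average(source$internal, source$region_map)
  labs <- as.integer(names(ra$means))
  nm <- source$region_map$label_names
  data.frame(label = labs,
             name = if (is.null(nm)) as.character(labs)
                    else unname(nm[as.character(labs)]),
             volume_ml = unname(ra$counts) * voxel_volume_ml(source$internal),
             concentration = unname(ra$means),
             iteration = iteration,
             stringsAsFactors = FALSE)
}
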