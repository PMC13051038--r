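#' 3D scalar field on a regular grid
#'
#' The basic volumetric container used throughout the package: a 3D array
#' plus the voxel size in mm and a grid origin.  Used for activity
#' concentration maps (MBq/mL), CT volumes (HU), density maps (g/cm3) and
#' linear attenuation coefficient maps (1/cm).  Physical coordinates are
#' voxel-centred: voxel (i, j, k) sits at
#' `origin + (c(i, j, k) - (dim + 1) / 2) * voxel_size`, i.e. the default
#' origin `c(0, 0, 0)` is the centre of the volume (and the rotation axis of
#' the projector runs through it along z).
#'
#' @param data numeric 3D array.
#' @param voxel_size voxel edge lengths in mm (length 3, or a scalar).
#' @param origin physical coordinate (mm) of the volume centre.
#' @return an object of class `volume_grid` with fields `data`,
#'   `voxel_size`, `origin`.
#' @export
volume_grid <- function(data, voxel_size, origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("'data' must be a 3D array")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("'voxel_size' must be positive and finite")
  structure(list(data = data,
                 voxel_size = voxel_size,
                 origin = rep_len(as.numeric(origin), 3L)),
            class = "volume_grid")
}

#' @export
dim.volume_grid <- function(x) dim(x$data)

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %s voxels of %s mm, range [%.4g, %.4g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

as_volume_grid <- function(x, like = NULL) {
  if (inherits(x, "volume_grid")) return(x)
  if (is.null(like)) stop("cannot coerce to volume_grid without a template")
  volume_grid(x, like$voxel_size, like$origin)
}

#' Voxel volume in mL
#' @param vol a [volume_grid] (or anything with a `voxel_size` field in mm).
#' @return scalar voxel volume in mL.
#' @export
voxel_volume_ml <- function(vol) prod(vol$voxel_size) / 1000

#' Total activity of a concentration volume
#'
#' Sum of concentration times voxel volume, in MBq for an input in MBq/mL.
#' @param vol a [volume_grid] of activity concentration (MBq/mL).
#' @return total activity (MBq).
#' @export
total_activity <- function(vol) sum(vol$data) * voxel_volume_ml(vol)

same_grid <- function(a, b, tol = 1e-9) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$voxel_size - b$voxel_size) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Read / write volumes as NIfTI
#'
#' Volumes are stored as NIfTI-1 with the voxel size carried in `pixdim` and
#' the origin in the sform translation.  Data are written as float64 so that
#' a write/read round trip is bit exact.
#'
#' @param vol a [volume_grid].
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume` returns a [volume_grid]; `write_volume` returns
#'   `path` invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  aff <- diag(4)
  diag(aff)[1:3] <- vol$voxel_size
  aff[1:3, 4] <- vol$origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img)[1:3])
  aff <- RNifti::xform(img)
  volume_grid(arr, abs(diag(aff)[1:3]), aff[1:3, 4])
}

#' Rigidly translate a volume
#'
#' Shifts a volume by a physical offset, used by the SPECT/CT misalignment
#' experiments.  Continuous maps (density, attenuation) use separable linear
#' interpolation; integer label maps must use nearest-neighbour so labels
#' stay integral.  Out-of-field values are zero.
#'
#' @param vol a [volume_grid].
#' @param offset_mm length-3 physical offset in mm (content moves by +offset).
#' @param order `"linear"` or `"nearest"`.
#' @return the translated [volume_grid].
#' @export
translate_volume <- function(vol, offset_mm, order = c("linear", "nearest")) {
  order <- match.arg(order)
  offset_mm <- rep_len(as.numeric(offset_mm), 3L)
  arr <- vol$data
  shift_vox <- offset_mm / vol$voxel_size
  if (order == "nearest") shift_vox <- round(shift_vox)
  for (ax in 1:3) {
    s <- shift_vox[ax]
    if (s == 0) next
    arr <- shift_axis_linear(arr, ax, s)
  }
  volume_grid(arr, vol$voxel_size, vol$origin)
}

# 1D fractional shift along one axis with linear interpolation, zero fill.
# Content moves by +s voxels: out[i] = in[i - s].
shift_axis_linear <- function(arr, axis, s) {
  n <- dim(arr)[axis]
  s0 <- floor(s); f <- s - s0
  take <- function(a, idx, axis) {
    ok <- idx >= 1L & idx <= n
    idx2 <- pmin(pmax(idx, 1L), n)
    sl <- switch(axis, a[idx2, , , drop = FALSE],
                 a[, idx2, , drop = FALSE], a[, , idx2, drop = FALSE])
    if (any(!ok)) {
      switch(axis, sl[!ok, , ] <- 0, sl[, !ok, ] <- 0, sl[, , !ok] <- 0)
    }
    sl
  }
  i <- seq_len(n)
  lo <- take(arr, i - s0, axis)
  if (f == 0) return(lo)
  hi <- take(arr, i - s0 - 1L, axis)
  (1 - f) * lo + f * hi
}

# Voxel-centre physical coordinates along each axis (mm).
grid_coords <- function(shape, voxel_size, origin = c(0, 0, 0)) {
  lapply(1:3, function(ax)
    origin[ax] + (seq_len(shape[ax]) - (shape[ax] + 1) / 2) * voxel_size[ax])
}
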