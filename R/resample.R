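#' Activity-conserving down-sampling to the emulated voxel size
#'
#' The projector sees the source at a coarser "emulated" voxel size, an
#' exact integer multiple of the fine internal grid that carries the region
#' map.  Down-sampling averages each factor-block of internal voxels, which
#' preserves concentration units and conserves total activity
#' (sum of concentration x voxel volume) exactly.
#'
#' @param internal a [volume_grid] at internal resolution (or a bare array).
#' @param factor integer length-3 block factor; the internal shape must be
#'   exactly divisible (no padding is applied).
#' @return a [volume_grid] at the emulated voxel size.
#' @export
downsample_to_emulated <- function(internal, factor) {
  factor <- as.integer(rep_len(factor, 3L))
  if (any(factor < 1L)) stop("'factor' must be positive integers")
  is_vg <- inherits(internal, "volume_grid")
  arr <- if (is_vg) internal$data else as.array(internal)
  n <- dim(arr)
  if (any(n %% factor != 0L))
    stop("internal shape (", paste(n, collapse = "x"),
         ") is not divisible by factor (", paste(factor, collapse = "x"), ")")
  m <- n %/% factor
  out <- block_reduce_mean(arr, factor)
  if (is_vg)
    volume_grid(out, internal$voxel_size * factor, internal$origin)
  else out
}

block_reduce_mean <- function(arr, factor) {
  n <- dim(arr); m <- n %/% factor
  dim(arr) <- c(factor[1], m[1], factor[2], m[2], factor[3], m[3])
  arr <- aperm(arr, c(1, 3, 5, 2, 4, 6))
  dim(arr) <- c(prod(factor), prod(m))
  out <- colMeans(arr)
  dim(out) <- m
  out
}

#' Partition emulated voxels back onto the internal grid
#'
#' Each internal voxel inherits the concentration of its parent emulated
#' voxel.  Concentration is constant within a block, so total activity is
#' conserved exactly; composing with [downsample_to_emulated()] is the
#' identity on block-constant volumes.
#'
#' @param emulated a [volume_grid] at emulated resolution (or a bare array).
#' @param factor integer length-3 block factor.
#' @return a [volume_grid] at internal resolution.
#' @export
upsample_to_internal <- function(emulated, factor) {
  factor <- as.integer(rep_len(factor, 3L))
  if (any(factor < 1L)) stop("'factor' must be positive integers")
  is_vg <- inherits(emulated, "volume_grid")
  arr <- if (is_vg) emulated$data else as.array(emulated)
  m <- dim(arr)
  out <- arr[rep(seq_len(m[1]), each = factor[1]),
             rep(seq_len(m[2]), each = factor[2]),
             rep(seq_len(m[3]), each = factor[3]), drop = FALSE]
  if (is_vg)
    volume_grid(out, emulated$voxel_size / factor, emulated$origin)
  else out
}
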