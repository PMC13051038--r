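#' @title Rotation-based forward and back projection
#' @name projector
#' @description
#' The system model is a rotation-based projector with bilinear
#' interpolation: for every view the source (and attenuation map) is
#' rotated so that the detector lies along +y of the rotated frame, each
#' (x, z) plane is multiplied by its accumulated attenuation factor and
#' convolved with the distance-dependent collimator-response kernel of that
#' plane, and the planes are summed toward the detector.  Scatter enters as
#' an additive term: the effective scatter source (activity convolved with
#' the scatter kernel) is projected the same way, optionally through a
#' rescaled attenuation map.  Multi-bed acquisitions project the source to
#' each axial bed position separately; back projection is the exact adjoint
#' (scatter excluded), built from the transposes of the same sparse
#' rotation/shift operators and the same symmetric kernels.
#'
#' Conventions (fixed for reproducibility):
#' * rotation centre is the matrix centre `(n + 1) / 2`; the source is
#'   rotated by the negative view angle, i.e. output voxel `p` samples the
#'   source at `c + R(angle) (p - c)` with bilinear weights, zero outside;
#' * plane `j` (y-index) lies at signed offset `yoff = (j - (ny+1)/2) * dy`
#'   from the rotation axis and its PSF distance is `orbit_radius - yoff`
#'   (planes behind the axis are farther from the detector);
#' * the attenuation factor of plane `j` is
#'   `exp(-dy_cm * (sum of mu over planes between j and the detector +
#'   half of plane j itself))`;
#' * expected counts are
#'   `calibration * time_per_view * voxel_volume_mL * sum of attenuated,
#'   convolved planes`, so with attenuation and PSF off one view conserves
#'   `total activity * time * calibration`.
NULL

# Sparse bilinear in-plane rotation operator (nx*ny x nx*ny).
rotation_sparse <- function(nx, ny, angle_deg) {
  th <- angle_deg * pi / 180
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  di <- rep(seq_len(nx) - cx, times = ny)
  dj <- rep(seq_len(ny) - cy, each = nx)
  u <- cx + cos(th) * di - sin(th) * dj
  v <- cy + sin(th) * di + cos(th) * dj
  i0 <- floor(u); j0 <- floor(v)
  fu <- u - i0; fv <- v - j0
  rows <- seq_len(nx * ny)
  ii <- c(i0, i0 + 1, i0, i0 + 1)
  jj <- c(j0, j0, j0 + 1, j0 + 1)
  ww <- c((1 - fu) * (1 - fv), fu * (1 - fv), (1 - fu) * fv, fu * fv)
  rr <- rep(rows, 4)
  ok <- ii >= 1 & ii <= nx & jj >= 1 & jj <= ny & ww > 0
  Matrix::sparseMatrix(i = rr[ok], j = ii[ok] + nx * (jj[ok] - 1),
                       x = ww[ok], dims = c(nx * ny, nx * ny))
}

# Sparse 1D axial shift operator (nz x nz): content moves by +shift_vox.
shift_sparse <- function(nz, shift_vox) {
  i <- seq_len(nz)
  pos <- i - shift_vox
  p0 <- floor(pos); f <- pos - p0
  rows <- c(i, i); cols <- c(p0, p0 + 1); w <- c(1 - f, f)
  ok <- cols >= 1 & cols <= nz & w > 0
  Matrix::sparseMatrix(i = rows[ok], j = cols[ok], x = w[ok],
                       dims = c(nz, nz))
}

apply_inplane <- function(op, arr) {
  d <- dim(arr)
  m <- arr; dim(m) <- c(d[1] * d[2], d[3])
  out <- as.matrix(op %*% m)
  dim(out) <- d
  out
}

apply_axial <- function(op, arr) {
  d <- dim(arr)
  m <- arr; dim(m) <- c(d[1] * d[2], d[3])
  out <- as.matrix(m %*% Matrix::t(op))
  dim(out) <- d
  out
}

attenuation_planes <- function(mu_rot, dy_cm) {
  d <- dim(mu_rot)
  att <- array(0, d)
  run <- matrix(0, d[1], d[3])
  for (j in d[2]:1) {
    mj <- mu_rot[, j, ]
    att[, j, ] <- exp(-dy_cm * (run + 0.5 * mj))
    run <- run + mj
  }
  att
}

# Precompute every per-view operator for a given geometry/model set.
# mu, mu_scatter: volume_grid on the emulated grid or NULL.
projector_context <- function(geometry, mu, res, vol_shape, voxel_size,
                              calibration = 1, mu_scatter = NULL) {
  nx <- vol_shape[1]; ny <- vol_shape[2]; nz <- vol_shape[3]
  if (abs(voxel_size[1] - voxel_size[2]) > 1e-9)
    stop("in-plane voxels must be square for the rotation-based projector")
  if (abs(geometry$pixel_size_mm[1] - voxel_size[1]) > 1e-6 ||
      abs(geometry$pixel_size_mm[2] - voxel_size[3]) > 1e-6)
    stop("detector pixel size must equal the emulated voxel size")
  if (geometry$detector_shape[1] != nx || geometry$detector_shape[2] != nz)
    stop("detector shape must equal the emulated matrix (x, z) shape")
  if (!is.null(mu)) {
    if (!identical(dim(mu$data), as.integer(vol_shape)))
      stop("attenuation map and source grids do not match")
    if (any(mu$data < 0)) stop("attenuation coefficients must be >= 0")
  }
  nb <- n_beds(geometry)
  dz <- voxel_size[3]
  shifts <- lapply(geometry$bed_axial_offsets_mm,
                   function(o) shift_sparse(nz, -o / dz))
  rot <- vector("list", geometry$n_views)
  rot_t <- vector("list", geometry$n_views)
  kx <- vector("list", geometry$n_views)
  kz <- vector("list", geometry$n_views)
  grp <- vector("list", geometry$n_views)
  yoff <- (seq_len(ny) - (ny + 1) / 2) * voxel_size[2]
  for (v in seq_len(geometry$n_views)) {
    rot[[v]] <- rotation_sparse(nx, ny, -geometry$angles[v])
    rot_t[[v]] <- Matrix::t(rot[[v]])
    if (!is.null(res) && res$enabled) {
      dists <- pmax(0, geometry$orbit_radius_mm[v] - yoff)
      step <- res$kernel_distance_step_mm
      dq <- if (is.null(step) || step <= 0) dists
            else pmax(0, round(dists / step) * step)
      g <- cumsum(c(1L, diff(dq) != 0))
      grp[[v]] <- as.integer(g)
      dg <- dq[!duplicated(g)]
      sig <- psf_fwhm(dg, res) * FWHM_TO_SIGMA
      kx[[v]] <- lapply(sig, psf_kernel_1d, pixel_mm = voxel_size[1],
                        truncation = res$kernel_truncation)
      kz[[v]] <- lapply(sig, psf_kernel_1d, pixel_mm = voxel_size[3],
                        truncation = res$kernel_truncation)
    } else {
      grp[[v]] <- rep(1L, ny)
      kx[[v]] <- list(1)
      kz[[v]] <- list(1)
    }
  }
  make_att <- function(muvol) {
    if (is.null(muvol)) return(NULL)
    dy_cm <- voxel_size[2] / 10
    lapply(seq_len(nb), function(b) {
      mus <- apply_axial(shifts[[b]], muvol$data)
      lapply(seq_len(geometry$n_views), function(v)
        attenuation_planes(apply_inplane(rot[[v]], mus), dy_cm))
    })
  }
  ctx <- new.env(parent = emptyenv())
  ctx$geometry <- geometry
  ctx$vol_shape <- as.integer(vol_shape)
  ctx$voxel_size <- voxel_size
  ctx$n_beds <- nb
  ctx$scale <- calibration * geometry$time_per_view_s * prod(voxel_size) / 1000
  ctx$rot <- rot; ctx$rot_t <- rot_t
  ctx$kx <- kx; ctx$kz <- kz; ctx$grp <- grp
  ctx$shifts <- shifts; ctx$shifts_t <- lapply(shifts, Matrix::t)
  ctx$att <- make_att(mu); ctx$att_scatter <- make_att(mu_scatter)
  ctx$mask <- geometry$detector_mask
  ctx$sens_cache <- list()
  ctx
}

# Forward-project an emulated-grid array; returns [nx, nz, n_views_sel, n_beds].
forward_emulated <- function(ctx, x, views = seq_len(ctx$geometry$n_views),
                             att = ctx$att) {
  d <- ctx$vol_shape
  out <- array(0, c(d[1], d[3], length(views), ctx$n_beds))
  for (b in seq_len(ctx$n_beds)) {
    xb <- if (ctx$n_beds == 1L && ctx$geometry$bed_axial_offsets_mm[1] == 0)
      x else apply_axial(ctx$shifts[[b]], x)
    for (vi in seq_along(views)) {
      v <- views[vi]
      xr <- apply_inplane(ctx$rot[[v]], xb)
      if (!is.null(att)) xr <- xr * att[[b]][[v]]
      P <- cpp_fwd_planes(xr, d, ctx$grp[[v]], ctx$kx[[v]], ctx$kz[[v]])
      P <- P * ctx$scale
      if (!is.null(ctx$mask)) P[!ctx$mask] <- 0
      out[, , vi, b] <- P
    }
  }
  out
}

# Exact adjoint of forward_emulated (scatter excluded).
back_emulated <- function(ctx, counts, views = seq_len(ctx$geometry$n_views),
                          att = ctx$att) {
  d <- ctx$vol_shape
  acc <- array(0, d)
  for (b in seq_len(ctx$n_beds)) {
    acc_b <- array(0, d)
    for (vi in seq_along(views)) {
      v <- views[vi]
      P <- counts[, , vi, b] * ctx$scale
      if (!is.null(ctx$mask)) P[!ctx$mask] <- 0
      cube <- cpp_adj_planes(P, d, ctx$grp[[v]], ctx$kx[[v]], ctx$kz[[v]])
      dim(cube) <- d
      if (!is.null(att)) cube <- cube * att[[b]][[v]]
      acc_b <- acc_b + apply_inplane(ctx$rot_t[[v]], cube)
    }
    acc <- acc + if (ctx$n_beds == 1L &&
                     ctx$geometry$bed_axial_offsets_mm[1] == 0)
      acc_b else apply_axial(ctx$shifts_t[[b]], acc_b)
  }
  acc
}

# Scatter projection term for the current emulated activity.
scatter_projection <- function(ctx, emu_vol, scat,
                               views = seq_len(ctx$geometry$n_views)) {
  if (is.null(scat) || !scat$enabled)
    return(0)
  ss <- scatter_source(emu_vol, scat)
  att <- if (!is.null(ctx$att_scatter)) ctx$att_scatter else ctx$att
  forward_emulated(ctx, ss$effective_source$data, views, att = att)
}

# Rescaled attenuation map for projecting the scatter source.
scatter_mu <- function(mu, activity_emulated, scat) {
  if (is.null(scat) || !scat$enabled || !scat$mean_scatter_energy_mode ||
      is.null(mu))
    return(NULL)
  ss <- scatter_source(activity_emulated, scat)
  w <- ss$mean_energy_weight$data
  volume_grid(mu$data * (1 + w * (scat$scatter_energy_mu_scale - 1)),
              mu$voxel_size, mu$origin)
}

#' Forward-project a source distribution
#'
#' @param source a [source_model] or a [volume_grid] already at the
#'   emulated voxel size.
#' @param mu attenuation map ([volume_grid], 1/cm) on the emulated grid, or
#'   `NULL` to disable attenuation.
#' @param geometry an [acquisition_geometry]; the detector grid must match
#'   the emulated (x, z) grid.
#' @param res a [resolution_model] or `NULL`.
#' @param scat a [scatter_model] or `NULL`.
#' @param calibration system sensitivity in counts per second per MBq.
#' @return a [projection_set] of expected counts.
#' @export
forward_project <- function(source, mu = NULL, geometry, res = NULL,
                            scat = NULL, calibration = 1) {
  emu <- if (inherits(source, "source_model")) emulated_volume(source)
         else source
  stopifnot(inherits(emu, "volume_grid"))
  mu_s <- scatter_mu(mu, emu, scat)
  ctx <- projector_context(geometry, mu, res, dim(emu$data), emu$voxel_size,
                           calibration, mu_scatter = mu_s)
  counts <- forward_emulated(ctx, emu$data)
  sp <- scatter_projection(ctx, emu, scat)
  projection_set(counts + sp, geometry)
}

#' Back-project projection data (adjoint of [forward_project()])
#'
#' The exact adjoint of the forward projector without the additive scatter
#' term.  The accumulation is computed on the emulated grid; when a
#' [source_model] template is supplied it is additionally partitioned onto
#' the template's internal grid (region averaging, where wanted, is applied
#' downstream by the reconstruction).
#'
#' @param projections a [projection_set].
#' @param mu,res,calibration as in [forward_project()].
#' @param source_template optional [source_model] defining the internal
#'   representation; its emulated grid must match the detector grid.
#' @param emulated_voxel_size voxel size of the emulated grid when no
#'   template is given (defaults to an isotropic grid from the detector
#'   pixels).
#' @return a [volume_grid] on the emulated grid, or a [source_model] when a
#'   template is given.
#' @export
back_project <- function(projections, mu = NULL, res = NULL,
                         source_template = NULL, calibration = 1,
                         emulated_voxel_size = NULL) {
  geometry <- projections$geometry
  if (!is.null(source_template)) {
    emu <- emulated_volume(source_template)
    shape <- dim(emu$data); vs <- emu$voxel_size
  } else {
    vs <- if (is.null(emulated_voxel_size))
      c(geometry$pixel_size_mm[1], geometry$pixel_size_mm[1],
        geometry$pixel_size_mm[2]) else rep_len(emulated_voxel_size, 3L)
    shape <- c(geometry$detector_shape[1], geometry$detector_shape[1],
               geometry$detector_shape[2])
  }
  ctx <- projector_context(geometry, mu, res, shape, vs, calibration)
  acc <- back_emulated(ctx, projections$counts)
  accv <- volume_grid(acc, vs)
  if (is.null(source_template)) return(accv)
  source_model(upsample_to_internal(accv, source_template$emulated_factor),
               region_map = source_template$region_map,
               emulated_factor = source_template$emulated_factor,
               mode = source_template$mode)
}
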