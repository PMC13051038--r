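#' Effective-scatter-source model
#'
#' Scatter is modelled in the forward projector: the activity distribution
#' is convolved with a scatter kernel and scaled by an amplitude, and the
#' resulting effective scatter source is projected and added to the primary
#' projection.  The default kernel is an isotropic mono-exponential
#' `exp(-r / decay)` normalized to unit sum, so the total effective source
#' equals `amplitude` times the total activity.
#'
#' `mean_scatter_energy_mode` selects a variant in which the scatter source
#' is projected through an attenuation map rescaled voxel-wise by a simple
#' two-energy weighting (`mu * (1 + w * (scatter_energy_mu_scale - 1))`,
#' where `w` in `[0, 1]` is the normalized blurred activity), reflecting
#' the lower mean energy of scattered photons.  This weighting is a
#' documented approximation and is not validated; the default projects the
#' scatter source through the photopeak map.
#'
#' @param amplitude scatter-to-primary amplitude (>= 0).
#' @param decay_mm decay length of the mono-exponential kernel.
#' @param kernel optional explicit 3D kernel (odd dimensions, non-negative);
#'   overrides the parametric form.
#' @param mean_scatter_energy_mode flag described above.
#' @param scatter_energy_mu_scale attenuation scale at the mean scatter
#'   energy relative to the photopeak.
#' @param enabled when `FALSE`, the effective source is zero.
#' @return object of class `scatter_model`.
#' @export
scatter_model <- function(amplitude = 0.2, decay_mm = 30, kernel = NULL,
                          mean_scatter_energy_mode = FALSE,
                          scatter_energy_mu_scale = 1.1,
                          enabled = TRUE) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (is.null(kernel) && decay_mm <= 0) stop("decay_mm must be > 0")
  if (!is.null(kernel)) {
    kernel <- as.array(kernel)
    if (any(kernel < 0)) stop("scatter kernel must be non-negative")
    if (any(dim(kernel) %% 2L == 0L)) stop("kernel dimensions must be odd")
    kernel <- kernel / sum(kernel)
  }
  structure(list(amplitude = amplitude, decay_mm = decay_mm, kernel = kernel,
                 mean_scatter_energy_mode = isTRUE(mean_scatter_energy_mode),
                 scatter_energy_mu_scale = scatter_energy_mu_scale,
                 enabled = isTRUE(enabled)),
            class = "scatter_model")
}

scatter_kernel_3d <- function(model, voxel_size) {
  if (!is.null(model$kernel)) return(model$kernel)
  h <- pmax(1L, ceiling(4 * model$decay_mm / voxel_size))
  co <- lapply(1:3, function(ax) (-h[ax]:h[ax]) * voxel_size[ax])
  r <- sqrt(outer(outer(co[[1]]^2, co[[2]]^2, "+"), co[[3]]^2, "+"))
  k <- exp(-r / model$decay_mm)
  k / sum(k)
}

# Zero-padded 3D FFT convolution ("same" output size).
conv3d_fft <- function(arr, kern) {
  da <- dim(arr); dk <- dim(kern)
  dp <- da + dk - 1L
  pa <- array(0, dp); pa[seq_len(da[1]), seq_len(da[2]), seq_len(da[3])] <- arr
  pk <- array(0, dp); pk[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- kern
  full <- Re(fft(fft(pa) * fft(pk), inverse = TRUE)) / prod(dp)
  off <- (dk - 1L) %/% 2L
  full[off[1] + seq_len(da[1]), off[2] + seq_len(da[2]), off[3] + seq_len(da[3])]
}

#' Effective scatter source from an activity distribution
#'
#' @param activity a [volume_grid] of activity concentration (>= 0).
#' @param model a [scatter_model].
#' @return list with `effective_source` (a [volume_grid]; zero when the
#'   model is disabled) and `mean_energy_weight` (a [volume_grid] in
#'   `[0, 1]`, or `NULL` unless `mean_scatter_energy_mode` is set).
#' @export
scatter_source <- function(activity, model) {
  if (any(activity$data < 0)) stop("activity must be >= 0")
  if (is.null(model) || !model$enabled) {
    return(list(effective_source = volume_grid(array(0, dim(activity$data)),
                                               activity$voxel_size,
                                               activity$origin),
                mean_energy_weight = NULL))
  }
  kern <- scatter_kernel_3d(model, activity$voxel_size)
  eff <- conv3d_fft(activity$data, kern)
  eff[eff < 0] <- 0  # FFT round-off
  w <- NULL
  if (model$mean_scatter_energy_mode) {
    mx <- max(eff)
    w <- volume_grid(if (mx > 0) eff / mx else eff * 0,
                     activity$voxel_size, activity$origin)
  }
  list(effective_source = volume_grid(model$amplitude * eff,
                                      activity$voxel_size, activity$origin),
       mean_energy_weight = w)
}
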