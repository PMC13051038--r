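#' Recovery-coefficient partial-volume correction
#'
#' @description
#' Limited spatial resolution makes the mean concentration measured in a
#' VOI an underestimate for hot objects (spill-out) contaminated by
#' background (spill-in).  Under a locally linear, translation-invariant
#' mixing model,
#'
#'   `C_img = RC * C_true + (1 - RC) * C_bkg`,
#'
#' a recovery coefficient `RC` in `(0, 1]` measured on phantoms inverts to
#'
#'   `C_pvc = (C_img - C_bkg * (1 - RC)) / RC`.
#'
#' Recovery is parameterized by the volume-to-surface ratio `eta` (a shape
#' descriptor more relevant than volume alone) and the OS-EM iteration
#' count `n`:
#'
#'   `RC(eta, n) = 1 / (1 + alpha_n * eta^(-beta_n))`,
#'
#' which increases monotonically with `eta`, tends to 1 for large objects
#' and to 0 for vanishing ones.  `alpha_n`, `beta_n` are obtained by
#' non-linear least squares from measured `(eta, RC)` pairs (e.g. from a
#' six-sphere phantom reconstruction).
#' @name pvc
NULL

#' Fit the recovery curve RC(eta) = 1 / (1 + alpha * eta^(-beta))
#'
#' Non-linear least squares with positivity bounds, started from
#' `alpha = 1, beta = 1` with two alternative multi-starts on failure.
#'
#' @param points data.frame or list with numeric `eta` (> 0, mm) and `rc`
#'   (in `(0, 1.2]`; slight overshoot in the data is allowed, the model
#'   itself never exceeds 1).
#' @param n iteration count this curve applies to (metadata).
#' @return object of class `recovery_curve`: `n`, `alpha`, `beta`,
#'   `residuals`, `eta_range`.
#' @export
fit_recovery_curve <- function(points, n = NA_integer_) {
  eta <- points$eta; rc <- points$rc
  if (length(eta) < 3) stop("at least 3 (eta, RC) points are required")
  if (any(eta <= 0)) stop("eta must be > 0")
  if (any(rc <= 0 | rc > 1.2)) stop("RC values must lie in (0, 1.2]")
  df <- data.frame(eta = eta, rc = rc)
  starts <- list(c(alpha = 1, beta = 1), c(alpha = 5, beta = 1.5),
                 c(alpha = 0.5, beta = 2))
  fit <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(rc ~ 1 / (1 + alpha * eta^(-beta)), data = df,
                        start = as.list(st),
                        lower = c(1e-8, 1e-8), upper = c(1e6, 50),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("recovery-curve fit did not converge after multi-start")
  cf <- coef(fit)
  structure(list(n = n, alpha = unname(cf["alpha"]), beta = unname(cf["beta"]),
                 residuals = rc - predict(fit),
                 eta_range = range(eta)),
            class = "recovery_curve")
}

#' Evaluate a recovery curve
#' @param curve a `recovery_curve` (or list with `alpha`, `beta`).
#' @param eta volume-to-surface ratio(s) in mm.
#' @return RC values in (0, 1).
#' @export
recovery_value <- function(curve, eta) {
  1 / (1 + curve$alpha * eta^(-curve$beta))
}

#' @export
print.recovery_curve <- function(x, ...) {
  cat(sprintf("<recovery_curve> n = %s: RC(eta) = 1/(1 + %.4g * eta^-%.4g), eta in [%.3g, %.3g]\n",
              x$n, x$alpha, x$beta, x$eta_range[1], x$eta_range[2]))
  invisible(x)
}

#' Serialize a recovery curve as JSON
#' @param curve a `recovery_curve`.
#' @param path JSON file path.
#' @return `read_recovery_curve` returns a `recovery_curve`.
#' @export
write_recovery_curve <- function(curve, path) {
  jsonlite::write_json(unclass(curve), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recovery_curve
#' @export
read_recovery_curve <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj, class = "recovery_curve")
}

#' Measure recovery coefficients from a calibrated reconstruction
#'
#' For each sphere VOI, `RC = (VOI mean - C_bkg) / (C_true - C_bkg)`,
#' paired with the VOI's volume-to-surface ratio.
#'
#' @param recon reconstructed [volume_grid] in MBq/mL.
#' @param true_concentration true sphere concentration (MBq/mL).
#' @param background_concentration true background concentration.
#' @param sphere_vois list of binary masks on `recon`'s grid (or on a grid
#'   refined from it; masks must match `recon` dimensions).
#' @param eta_method surface method for [estimate_eta()].
#' @return data.frame with `eta`, `rc`, `volume_ml`.
#' @export
measure_recovery <- function(recon, true_concentration,
                             background_concentration, sphere_vois,
                             eta_method = "mesh") {
  if (true_concentration == background_concentration)
    stop("RC undefined when truth equals background")
  out <- lapply(sphere_vois, function(m) {
    m <- as.array(m) != 0
    st <- estimate_eta(m, recon$voxel_size, method = eta_method)
    rc <- (mean(recon$data[m]) - background_concentration) /
      (true_concentration - background_concentration)
    data.frame(eta = st$eta_mm, rc = rc, volume_ml = st$volume_ml)
  })
  do.call(rbind, out)
}

# k-fold 6-connected binary dilation.
dilate6 <- function(mask, k) {
  m <- as.array(mask) != 0
  for (i in seq_len(k)) {
    m <- m | shift_pad0(m, 1, 0, 0) | shift_pad0(m, -1, 0, 0) |
      shift_pad0(m, 0, 1, 0) | shift_pad0(m, 0, -1, 0) |
      shift_pad0(m, 0, 0, 1) | shift_pad0(m, 0, 0, -1)
  }
  m
}

#' Background VOI as a dilation shell
#'
#' The background concentration for spill-in correction is sampled in the
#' logical difference between two successive dilations of the object VOI:
#' `dilate(voi, outer) & !dilate(voi, inner)` with a 6-connected
#' structuring element.  Never intersects the object.
#'
#' @param voi binary object mask.
#' @param inner_dilation inner dilation radius in voxels (>= 1).
#' @param outer_dilation outer dilation radius in voxels (> inner).
#' @return logical mask of the shell.
#' @export
background_voi <- function(voi, inner_dilation = 1L, outer_dilation = 3L) {
  if (!(outer_dilation > inner_dilation && inner_dilation >= 1))
    stop("need outer_dilation > inner_dilation >= 1")
  voi <- as.array(voi) != 0
  shell <- dilate6(voi, outer_dilation) & !dilate6(voi, inner_dilation)
  if (!any(shell))
    stop("background shell is empty (object touches the field-of-view edge?)")
  shell
}

#' Apply recovery-coefficient PVC with spill-in correction
#'
#' `C_pvc = (C_img - C_bkg * (1 - rc)) / rc`; the exact inverse of the
#' mixing model `C_img = rc * C_true + (1 - rc) * C_bkg`.  For cold
#' regions (`C_img < C_bkg`) the result may fall below the background;
#' that is allowed.
#'
#' @param c_img VOI mean concentration measured in the image (>= 0).
#' @param c_bkg background concentration (>= 0).
#' @param rc recovery coefficient in (0, 1].
#' @return corrected concentration(s).
#' @export
apply_pvc <- function(c_img, c_bkg, rc) {
  if (any(rc <= 0)) stop("rc must be > 0")
  if (any(rc > 1)) rc <- pmin(rc, 1)
  if (any(c_img < 0) || any(c_bkg < 0)) stop("concentrations must be >= 0")
  (c_img - c_bkg * (1 - rc)) / rc
}
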