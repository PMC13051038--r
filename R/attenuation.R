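#' Attenuation model: CT number to density to attenuation coefficient
#'
#' CT volumes in Hounsfield units are rescaled to mass density via a
#' multi-linear-segment relationship, and density maps are rescaled to
#' linear attenuation coefficients by thresholding into materials (soft
#' tissue vs bone) and multiplying by the material's mass attenuation
#' coefficient at the imaging energy.  The default table anchors water at
#' HU = 0 (1.0 g/cm3) and air at HU = -1000 (0 g/cm3), and uses mass
#' attenuation coefficients for the 208 keV photopeak of 177Lu.
#'
#' @param hu_breakpoints strictly increasing HU breakpoints.
#' @param densities densities (g/cm3) at the breakpoints; linear in
#'   between, clamped at the ends.
#' @param material_threshold density (g/cm3) separating soft tissue from
#'   bone.
#' @param mass_attenuation named vector `c(soft = ..., bone = ...)` in
#'   cm2/g at the imaging energy.
#' @return object of class `attenuation_model`.
#' @export
attenuation_model <- function(hu_breakpoints = c(-1000, 0, 1000, 3000),
                              densities = c(0, 1.0, 1.55, 2.7),
                              material_threshold = 1.15,
                              mass_attenuation = c(soft = 0.136, bone = 0.146)) {
  if (any(diff(hu_breakpoints) <= 0))
    stop("HU breakpoints must be strictly increasing")
  if (length(densities) != length(hu_breakpoints))
    stop("breakpoints and densities differ in length")
  if (any(densities < 0)) stop("densities must be >= 0")
  if (any(mass_attenuation <= 0)) stop("mass attenuation must be > 0")
  if (!all(c("soft", "bone") %in% names(mass_attenuation)))
    stop("mass_attenuation needs 'soft' and 'bone' entries")
  structure(list(hu_breakpoints = as.numeric(hu_breakpoints),
                 densities = as.numeric(densities),
                 material_threshold = as.numeric(material_threshold),
                 mass_attenuation = mass_attenuation),
            class = "attenuation_model")
}

#' Convert a CT volume (HU) to density (g/cm3)
#'
#' Voxel-wise piecewise-linear interpolation of the model's segment table,
#' clamped at the table ends and floored at 0.
#'
#' @param ct a [volume_grid] in HU.
#' @param model an [attenuation_model].
#' @return a [volume_grid] in g/cm3.
#' @export
hu_to_density <- function(ct, model = attenuation_model()) {
  if (any(!is.finite(ct$data))) stop("CT volume contains non-finite values")
  d <- approx(model$hu_breakpoints, model$densities, xout = as.vector(ct$data),
              rule = 2)$y
  d[d < 0] <- 0
  volume_grid(array(d, dim = dim(ct$data)), ct$voxel_size, ct$origin)
}

#' Convert a density map to linear attenuation coefficients (1/cm)
#'
#' Voxels are assigned a material by thresholding the density, then
#' `mu = density * mass_attenuation[material]`.
#'
#' @param density a [volume_grid] in g/cm3 (>= 0).
#' @param model an [attenuation_model].
#' @return a [volume_grid] in 1/cm.
#' @export
density_to_attenuation <- function(density, model = attenuation_model()) {
  d <- density$data
  if (any(d < 0)) stop("density must be >= 0")
  mu <- d * ifelse(d >= model$material_threshold,
                   model$mass_attenuation[["bone"]],
                   model$mass_attenuation[["soft"]])
  volume_grid(mu, density$voxel_size, density$origin)
}
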