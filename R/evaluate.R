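#' Relative difference between two estimates
#'
#' `delta = 2 * (c_rv - c_cuv) / (c_rv + c_cuv)`, the symmetric relative
#' difference used to compare regional-voxel and PVC-corrected
#' cuboid-voxel concentrations; bounded in (-2, 2) and antisymmetric under
#' argument swap.
#'
#' @param c_rv,c_cuv_pvc concentrations with `c_rv + c_cuv_pvc > 0`.
#' @return delta (dimensionless).
#' @export
relative_difference <- function(c_rv, c_cuv_pvc) {
  s <- c_rv + c_cuv_pvc
  if (any(s == 0)) stop("zero denominator in relative difference")
  2 * (c_rv - c_cuv_pvc) / s
}

#' Relative error of an estimate against a reference
#'
#' `epsilon = c_est / c_ref - 1`.
#'
#' @param c_est estimated concentration(s).
#' @param c_ref reference concentration (> 0).
#' @return epsilon (dimensionless).
#' @export
relative_error <- function(c_est, c_ref) {
  if (any(c_ref <= 0)) stop("c_ref must be > 0")
  c_est / c_ref - 1
}

#' Mean and SD over noise realizations
#'
#' Aggregates per-realization records by structure and method: mean and
#' sample SD of the concentration and of the relative error.
#'
#' @param records data.frame with columns `name` (or `label`), `method`,
#'   `concentration` and optionally `epsilon`, one row per realization.
#' @return data.frame with per-group `n`, `mean_concentration`,
#'   `sd_concentration`, and `mean_epsilon`, `sd_epsilon` when present.
#' @export
summarize_estimates <- function(records) {
  key <- interaction(records$name, records$method, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    g <- records[key == k, , drop = FALSE]
    out <- data.frame(name = g$name[1], method = g$method[1], n = nrow(g),
                      mean_concentration = mean(g$concentration),
                      sd_concentration = if (nrow(g) > 1) sd(g$concentration)
                                         else 0,
                      stringsAsFactors = FALSE)
    if (!is.null(g$epsilon)) {
      out$mean_epsilon <- mean(g$epsilon)
      out$sd_epsilon <- if (nrow(g) > 1) sd(g$epsilon) else 0
    }
    out
  })
  do.call(rbind, rows)
}

#' Structures in the periphery of the transaxial field of view
#'
#' Labels whose centroid lies within `margin_mm` of the transaxial FOV
#' edge (structures there are conventionally excluded from analysis).
#'
#' @param map a [region_map].
#' @param margin_mm exclusion margin from the transaxial FOV boundary.
#' @return integer vector of peripheral labels (background excluded).
#' @export
peripheral_labels <- function(map, margin_mm = 20) {
  d <- dim(map$labels); vs <- map$voxel_size
  co <- grid_coords(d, vs)
  half <- d[1:2] * vs[1:2] / 2
  labs <- structure_labels(map)
  out <- integer(0)
  for (l in labs) {
    idx <- which(map$labels == l, arr.ind = TRUE)
    cen <- c(mean(co[[1]][idx[, 1]]), mean(co[[2]][idx[, 2]]))
    if (any(abs(cen) > half - margin_mm)) out <- c(out, l)
  }
  out
}

# Mean of a reconstruction over each labelled region (internal grid).
voi_means <- function(recon_internal, map, labels) {
  vapply(labels, function(l)
    mean(recon_internal$data[map$labels == l]), numeric(1))
}

# Downsample a binary internal-grid mask to the emulated grid (>= 0.5
# occupancy), used for background shells at a physically sensible scale.
emulated_mask <- function(mask, fac) {
  block_reduce_mean(as.array(mask) * 1, as.integer(rep_len(fac, 3L))) >= 0.5
}

#' Recovery curve from a sphere-phantom acquisition
#'
#' Simulates (or accepts) an essentially noise-free acquisition of a
#' six-sphere phantom, reconstructs it with cuboid voxels, measures the
#' recovery coefficient of every sphere against the known concentrations
#' and fits the RC(eta) model.
#'
#' @param phantom list with `activity`, `density` ([volume_grid], internal
#'   grid) and `region_map` as from [make_nema_phantom()].
#' @param geometry an [acquisition_geometry].
#' @param res,scat,att_model system models.
#' @param calibration counts per second per MBq.
#' @param emulated_factor internal-to-emulated factor.
#' @param config cuboid-voxel [recon_config]; its `n_iterations` is
#'   recorded as the curve's `n`.
#' @param eta_method surface method for [estimate_eta()].
#' @return list with `curve` (a `recovery_curve`), `points` (measured
#'   `(eta, rc)` data) and `recon` (the reconstructed [source_model]).
#' @export
derive_recovery_curve <- function(phantom, geometry, res = resolution_model(),
                                  scat = NULL,
                                  att_model = attenuation_model(),
                                  calibration = 10,
                                  emulated_factor = c(1L, 1L, 1L),
                                  config = recon_config(n_iterations = 40L),
                                  eta_method = "mesh") {
  truth <- source_model(phantom$activity, phantom$region_map,
                        emulated_factor = emulated_factor, mode = "rv")
  mu <- density_to_attenuation(downsample_to_emulated(phantom$density,
                                                      emulated_factor),
                               att_model)
  clean <- forward_project(truth, mu, geometry, res, scat, calibration)
  tmpl <- source_model(volume_grid(array(1, dim(phantom$activity$data)),
                                   phantom$activity$voxel_size),
                       emulated_factor = emulated_factor, mode = "cuv")
  fit <- osem(clean, mu, res, scat, tmpl, config, calibration)
  map <- phantom$region_map
  labs <- structure_labels(map)
  truth_means <- region_average(phantom$activity, map)$means
  bkg_true <- truth_means[as.character(map$background_label)]
  vois <- lapply(labs, function(l) map$labels == l)
  pts <- measure_recovery(fit$source$internal,
                          true_concentration = max(phantom$activity$data),
                          background_concentration = bkg_true,
                          sphere_vois = vois, eta_method = eta_method)
  list(curve = fit_recovery_curve(pts, n = config$n_iterations),
       points = pts, recon = fit$source)
}

# Structure labels of a region map: everything except unlabelled voxels,
# the background region, and nuisance regions named "air".
structure_labels <- function(map) {
  labs <- setdiff(sort(unique(as.vector(map$labels))),
                  c(0L, map$background_label))
  if (!is.null(map$label_names))
    labs <- labs[map$label_names[as.character(labs)] != "air"]
  labs
}

# Per-label VOI geometry (volume, eta, emulated background shell), shared
# across noise realizations of one region map.
voi_geometry <- function(map, emulated_factor, eta_method = "mesh",
                         bkg_shell = c(1L, 3L)) {
  labs <- structure_labels(map)
  out <- lapply(labs, function(l) {
    mask_int <- map$labels == l
    st <- estimate_eta(mask_int, map$voxel_size, method = eta_method)
    mask_emu <- emulated_mask(mask_int, emulated_factor)
    list(label = l, stats = st,
         shell = background_voi(mask_emu, bkg_shell[1], bkg_shell[2]))
  })
  names(out) <- as.character(labs)
  out
}

# Shared single-realization estimation: r.v., cu.v. raw and cu.v. + PVC
# against one projection set, with (possibly shifted) mu and region map.
estimate_all_methods <- function(projections, mu, map, res, scat,
                                 calibration, emulated_factor,
                                 rv_config, cuv_config, rc_curve,
                                 eta_method = "mesh",
                                 bkg_shell = c(1L, 3L), .ctx = NULL,
                                 voi_geom = NULL) {
  vs_int <- map$voxel_size
  di <- dim(map$labels)
  if (is.null(.ctx))
    .ctx <- projector_context(projections$geometry, mu, res,
                              di %/% emulated_factor,
                              vs_int * emulated_factor, calibration)
  tmpl_rv <- source_model(volume_grid(array(1, di), vs_int), map,
                          emulated_factor = emulated_factor, mode = "rv")
  fit_rv <- osem(projections, mu, res, scat, tmpl_rv, rv_config, calibration,
                 .ctx = .ctx)
  est_rv <- extract_estimates(fit_rv$source, rv_config$n_iterations)
  tmpl_cu <- source_model(volume_grid(array(1, di), vs_int),
                          emulated_factor = emulated_factor, mode = "cuv")
  fit_cu <- osem(projections, mu, res, scat, tmpl_cu, cuv_config, calibration,
                 .ctx = .ctx)
  recon_int <- fit_cu$source$internal
  recon_emu <- emulated_volume(fit_cu$source)
  if (is.null(voi_geom))
    voi_geom <- voi_geometry(map, emulated_factor, eta_method, bkg_shell)
  labs <- vapply(voi_geom, `[[`, integer(1), "label")
  c_img <- voi_means(recon_int, map, labs)
  rows <- lapply(seq_along(labs), function(i) {
    l <- labs[i]
    st <- voi_geom[[i]]$stats
    c_bkg <- mean(recon_emu$data[voi_geom[[i]]$shell])
    rc <- if (is.null(rc_curve)) 1 else recovery_value(rc_curve, st$eta_mm)
    nm <- if (is.null(map$label_names)) as.character(l)
          else unname(map$label_names[as.character(l)])
    data.frame(label = l, name = nm, volume_ml = st$volume_ml,
               eta_mm = st$eta_mm,
               method = c("rv", "cuv_pvc", "cuv_raw"),
               concentration = unname(c(est_rv$concentration[est_rv$label == l],
                                        apply_pvc(c_img[i], c_bkg, rc),
                                        c_img[i])),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full method-comparison experiment on a synthetic phantom
#'
#' One command regenerates the comparison of regional voxels, cuboid
#' voxels with recovery-coefficient PVC, and uncorrected cuboid voxels:
#' the phantom is projected noise free through the full system model,
#' Poisson noise realizations are drawn, every realization is estimated
#' with all three methods, and relative errors against the phantom truth
#' are aggregated over realizations.  Deterministic given `seed`
#' (realization `i` uses `seed + i`).
#'
#' @param phantom list with `activity`, `density`, `region_map` on the
#'   internal grid.
#' @param geometry an [acquisition_geometry] matching the emulated grid.
#' @param rc_curve a `recovery_curve` for the PVC arm (e.g. from
#'   [derive_recovery_curve()]).
#' @param res,scat,att_model system models.
#' @param calibration counts per second per MBq.
#' @param emulated_factor internal-to-emulated integer factor.
#' @param n_realizations number of Poisson noise realizations.
#' @param seed base seed (required).
#' @param rv_config,cuv_config [recon_config]s for the two arms.
#' @param eta_method surface method for [estimate_eta()].
#' @return list with `records` (per-realization tidy table incl. column
#'   `epsilon`), `summary` (via [summarize_estimates()]), `truth` (per-
#'   label reference concentrations), `clean_projections`.
#' @export
compare_methods_report <- function(phantom, geometry, rc_curve,
                                   res = resolution_model(), scat = NULL,
                                   att_model = attenuation_model(),
                                   calibration = 10,
                                   emulated_factor = c(1L, 1L, 1L),
                                   n_realizations = 10L, seed,
                                   rv_config = recon_config(n_iterations = 8L),
                                   cuv_config = recon_config(n_iterations = 40L),
                                   eta_method = "mesh") {
  map <- phantom$region_map
  truth_sm <- source_model(phantom$activity, map,
                           emulated_factor = emulated_factor, mode = "rv")
  mu <- density_to_attenuation(downsample_to_emulated(phantom$density,
                                                      emulated_factor),
                               att_model)
  clean <- forward_project(truth_sm, mu, geometry, res, scat, calibration)
  truth_means <- region_average(phantom$activity, map)$means
  ctx <- projector_context(geometry, mu, res,
                           dim(map$labels) %/% emulated_factor,
                           map$voxel_size * emulated_factor, calibration)
  vg <- voi_geometry(map, emulated_factor, eta_method)
  recs <- lapply(seq_len(n_realizations), function(i) {
    noisy <- add_poisson_noise(clean, seed + i)
    df <- estimate_all_methods(noisy, mu, map, res, scat, calibration,
                               emulated_factor, rv_config, cuv_config,
                               rc_curve, eta_method, .ctx = ctx,
                               voi_geom = vg)
    df$realization <- i
    df
  })
  records <- do.call(rbind, recs)
  records$epsilon <- relative_error(
    records$concentration, truth_means[as.character(records$label)])
  list(records = records, summary = summarize_estimates(records),
       truth = truth_means, clean_projections = clean)
}

#' SPECT/CT misalignment sensitivity sweep
#'
#' Emulates misregistration between the emission data and the CT-derived
#' maps: for each offset the density map (linear interpolation) and the
#' region map / VOIs (nearest neighbour, labels stay integral) are
#' translated before estimation while the projections stay fixed, and the
#' relative error of each method and structure is recorded.  Offset 0
#' reproduces the unshifted pipeline exactly.
#'
#' @param phantom list with `activity`, `density`, `region_map` (internal
#'   grid).
#' @param geometry an [acquisition_geometry].
#' @param rc_curve `recovery_curve` for the PVC arm.
#' @param offsets_mm offsets applied along each axis; should be symmetric
#'   about 0 and include 0.
#' @param axes subset of `c("x", "y", "z")`.
#' @param res,scat,att_model,calibration,emulated_factor as in
#'   [compare_methods_report()].
#' @param seed seed for the single fixed noise realization (use `NULL`
#'   for a noise-free sweep).
#' @param rv_config,cuv_config [recon_config]s.
#' @param eta_method surface method for [estimate_eta()].
#' @return list with `records` (tidy table: axis, offset_mm, structure,
#'   method, concentration, epsilon) and `truth`.
#' @export
misalignment_experiment <- function(phantom, geometry, rc_curve,
                                    offsets_mm = seq(-10, 10, by = 2),
                                    axes = "x",
                                    res = resolution_model(), scat = NULL,
                                    att_model = attenuation_model(),
                                    calibration = 10,
                                    emulated_factor = c(1L, 1L, 1L),
                                    seed = NULL,
                                    rv_config = recon_config(n_iterations = 8L),
                                    cuv_config = recon_config(n_iterations = 40L),
                                    eta_method = "mesh") {
  map <- phantom$region_map
  truth_sm <- source_model(phantom$activity, map,
                           emulated_factor = emulated_factor, mode = "rv")
  mu0 <- density_to_attenuation(downsample_to_emulated(phantom$density,
                                                       emulated_factor),
                                att_model)
  clean <- forward_project(truth_sm, mu0, geometry, res, scat, calibration)
  proj <- if (is.null(seed)) clean else add_poisson_noise(clean, seed)
  truth_means <- region_average(phantom$activity, map)$means
  ax_idx <- match(axes, c("x", "y", "z"))
  recs <- list()
  for (a in seq_along(axes)) {
    for (off in offsets_mm) {
      ov <- c(0, 0, 0); ov[ax_idx[a]] <- off
      den_s <- translate_volume(phantom$density, ov, order = "linear")
      lab_s <- translate_volume(volume_grid(map$labels + 0, map$voxel_size),
                                ov, order = "nearest")
      map_s <- region_map(round(lab_s$data), map$voxel_size,
                          label_names = map$label_names,
                          background_label = map$background_label,
                          unlabeled_slices = map$unlabeled_slices)
      mu_s <- density_to_attenuation(downsample_to_emulated(den_s,
                                                            emulated_factor),
                                     att_model)
      df <- estimate_all_methods(proj, mu_s, map_s, res, scat, calibration,
                                 emulated_factor, rv_config, cuv_config,
                                 rc_curve, eta_method)
      df$axis <- axes[a]
      df$offset_mm <- off
      recs[[length(recs) + 1L]] <- df
    }
  }
  records <- do.call(rbind, recs)
  records$epsilon <- relative_error(
    records$concentration, truth_means[as.character(records$label)])
  list(records = records, truth = truth_means)
}

#' Write / read evaluation tables as CSV
#'
#' Plain CSV round trip for result tables (row names dropped).
#' @param df a data.frame.
#' @param path CSV path.
#' @return `read_results_csv` returns the data.frame.
#' @export
write_results_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results_csv
#' @export
read_results_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
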