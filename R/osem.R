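#' OS-EM reconstruction configuration
#'
#' Defaults follow common practice for quantitative 177Lu SPECT: ten
#' subsets, with 40 iterations for cuboid voxels and 8 for regional voxels
#' (regional estimates stabilize much earlier).  Views are assigned to
#' subsets round-robin by angle index with stride `n_subsets`, which
#' maximizes the angular separation within each subset; the initial
#' estimate is a uniform positive constant.
#'
#' @param n_iterations number of full iterations (each visits all subsets).
#' @param n_subsets number of ordered subsets (1 = MLEM).
#' @param initial_value uniform initial concentration (> 0).
#' @param nonneg_floor small positive floor applied after each update.
#' @param convergence_log when `TRUE`, evaluate the Poisson log-likelihood
#'   of the full data after every iteration (one extra forward projection
#'   per iteration).
#' @return object of class `recon_config`.
#' @export
recon_config <- function(n_iterations = 40L, n_subsets = 10L,
                         initial_value = 1, nonneg_floor = 1e-12,
                         convergence_log = FALSE) {
  if (initial_value <= 0) stop("initial_value must be > 0")
  if (n_subsets < 1L) stop("n_subsets must be >= 1")
  structure(list(n_iterations = as.integer(n_iterations),
                 n_subsets = as.integer(n_subsets),
                 initial_value = as.numeric(initial_value),
                 nonneg_floor = as.numeric(nonneg_floor),
                 convergence_log = isTRUE(convergence_log)),
            class = "recon_config")
}

subset_views <- function(n_views, n_subsets) {
  lapply(seq_len(n_subsets),
         function(s) as.integer(seq.int(s, n_views, by = n_subsets)))
}

#' One multiplicative EM update
#'
#' The elementary update `x <- x * At(y / (A x + s)) / At(1)` shared by
#' MLEM and OS-EM, exposed for use with arbitrary linear operators (e.g. a
#' hand-written system matrix).  Where `A x + s = 0` the ratio is taken as
#' 0 (consistent with `y = 0` there); elements with zero sensitivity are
#' frozen at their current value.
#'
#' @param x current estimate (numeric vector/array, >= 0).
#' @param y measured data.
#' @param forward function mapping `x` to expected data.
#' @param backward adjoint of `forward`.
#' @param sensitivity `backward(1)`, precomputed.
#' @param scatter additive expected-scatter term (default 0).
#' @param floor non-negativity floor.
#' @return updated estimate, same shape as `x`.
#' @export
em_update <- function(x, y, forward, backward, sensitivity, scatter = 0,
                      floor = 1e-12) {
  yhat <- forward(x) + scatter
  ratio <- y * 0
  pos <- yhat > 0
  ratio[pos] <- y[pos] / yhat[pos]
  num <- backward(ratio)
  upd <- x
  ok <- sensitivity > 0
  upd[ok] <- pmax(x[ok] * num[ok] / sensitivity[ok], floor)
  upd
}

# Parent emulated-voxel linear index for every internal voxel.
emulated_parent_index <- function(di, fac) {
  de <- di %/% fac
  ei <- ceiling(seq_len(di[1]) / fac[1])
  ej <- ceiling(seq_len(di[2]) / fac[2])
  ek <- ceiling(seq_len(di[3]) / fac[3])
  as.vector(outer(outer(ei, (ej - 1) * de[1], "+"),
                  (ek - 1) * de[1] * de[2], "+"))
}

#' OS-EM estimation over cuboid- or regional-voxel source models
#'
#' Runs ordered-subsets expectation maximization with the rotation-based
#' projector.  The template's mode decides the behaviour: for cuboid
#' voxels the update is the standard voxel-wise multiplicative step on the
#' emulated grid; for regional voxels both the back-projected ratio and
#' the sensitivity are partitioned onto the internal grid and summed
#' within each labelled region *before* taking their quotient (the
#' maximum-likelihood update for region basis functions -- a plain average
#' of the ratio image alone would not reduce to the regional ML update),
#' so the internal representation stays region-wise constant after every
#' update.  Label-0 voxels keep voxel-wise updates at the emulated size.
#' The additive scatter term is recomputed from the current estimate at
#' each subset and held fixed inside the denominator (it is never
#' deconvolved).
#'
#' @param projections a [projection_set] (counts >= 0).
#' @param mu attenuation map on the emulated grid or `NULL`.
#' @param res a [resolution_model] or `NULL`.
#' @param scat a [scatter_model] or `NULL`.
#' @param source_template a [source_model] providing grid, mode and region
#'   map; its voxel values are ignored.
#' @param config a [recon_config].
#' @param calibration counts per second per MBq.
#' @param track_map optional [region_map] on the internal grid used, for
#'   cuboid-voxel reconstructions, to log per-iteration VOI means (for
#'   regional voxels the template's own map is used).
#' @return list with `source` (the estimated [source_model]), `estimates`
#'   (per-iteration regional estimates when a region/track map is
#'   available, else `NULL`) and `convergence` (data.frame: `iteration`,
#'   `max_rel_change` of the tracked means between successive iterations,
#'   `log_likelihood` when `convergence_log`).
#' @export
osem <- function(projections, mu = NULL, res = NULL, scat = NULL,
                 source_template, config = recon_config(),
                 calibration = 1, track_map = NULL, .ctx = NULL) {
  stopifnot(inherits(projections, "projection_set"),
            inherits(source_template, "source_model"))
  geometry <- projections$geometry
  y <- projections$counts
  if (any(y < 0)) stop("projections must be >= 0")
  emu0 <- emulated_volume(source_template)
  vs <- emu0$voxel_size
  shape <- dim(emu0$data)
  ctx <- if (!is.null(.ctx)) .ctx else {
    mu_s <- scatter_mu(mu, emu0, scat)
    projector_context(geometry, mu, res, shape, vs, calibration,
                      mu_scatter = mu_s)
  }
  subsets <- subset_views(geometry$n_views, config$n_subsets)
  key <- as.character(config$n_subsets)
  if (is.null(ctx$sens_cache[[key]])) {
    ctx$sens_cache[[key]] <- lapply(subsets, function(vw) {
      o <- array(1, c(shape[1], shape[3], length(vw), ctx$n_beds))
      back_emulated(ctx, o, vw)
    })
  }
  sens <- ctx$sens_cache[[key]]
  rv <- source_template$mode == "rv"
  fac <- source_template$emulated_factor
  rmap <- if (rv) source_template$region_map else track_map
  x <- array(config$initial_value, shape)

  if (rv) {
    di <- dim(source_template$internal$data)
    nfine <- prod(fac)
    lab_i <- as.vector(rmap$labels)
    labelled <- lab_i > 0L
    labs <- sort(unique(lab_i[labelled]))
    e_idx <- emulated_parent_index(di, fac)
    # region-by-emulated-voxel membership counts; all region sums over the
    # internal grid reduce to sparse products with emulated-grid vectors
    B <- Matrix::sparseMatrix(i = match(lab_i[labelled], labs),
                              j = e_idx[labelled], x = 1,
                              dims = c(length(labs), prod(shape)))
    n0_e <- tabulate(e_idx[!labelled], prod(shape))
    den_m <- lapply(sens, function(d) as.vector(B %*% as.vector(d)))
    conc <- rep(config$initial_value, length(labs))
    x0_e <- rep(config$initial_value, prod(shape))
    emu_from_parts <- function() {
      v <- (as.vector(Matrix::crossprod(B, conc)) + n0_e * x0_e) / nfine
      dim(v) <- shape
      v
    }
    x <- emu_from_parts()
    vol_counts <- tabulate(match(lab_i[labelled], labs), length(labs))
    fine_vox_ml <- prod(vs / fac) / 1000
    region_names <- if (is.null(rmap$label_names)) as.character(labs)
                    else unname(rmap$label_names[as.character(labs)])
  }
  tracked_means <- function() {
    if (rv) conc
    else if (!is.null(rmap)) {
      xi <- upsample_to_internal(x, fac)
      region_average(volume_grid(xi, vs / fac), rmap)$means
    } else mean(x)
  }
  cuv_estimates <- function(it) {
    m <- tracked_means()
    labs_t <- as.integer(names(m))
    cnts <- tabulate(factor(rmap$labels[rmap$labels > 0L], levels = labs_t))
    data.frame(label = labs_t,
               name = if (is.null(rmap$label_names)) as.character(labs_t)
                      else unname(rmap$label_names[as.character(labs_t)]),
               volume_ml = cnts * prod(vs / fac) / 1000,
               concentration = unname(m), iteration = it,
               stringsAsFactors = FALSE)
  }
  emu_vol <- function(xarr) volume_grid(xarr, vs, emu0$origin)
  est_log <- list(); conv <- list(); prev_means <- NULL
  for (it in seq_len(config$n_iterations)) {
    for (s in seq_along(subsets)) {
      vw <- subsets[[s]]
      sp <- scatter_projection(ctx, emu_vol(x), scat, vw)
      yhat <- forward_emulated(ctx, x, vw) + sp
      ys <- y[, , vw, , drop = FALSE]
      ratio <- ys * 0
      pos <- yhat > 0
      ratio[pos] <- ys[pos] / yhat[pos]
      num <- back_emulated(ctx, ratio, vw)
      den <- sens[[s]]
      if (rv) {
        num_m <- as.vector(B %*% as.vector(num))
        dm <- den_m[[s]]
        reg_ratio <- ifelse(dm > 0, num_m / dm, 1)
        conc <- pmax(conc * reg_ratio, config$nonneg_floor)
        r0 <- ifelse(den > 0, num / den, 1)
        x0_e <- pmax(x0_e * as.vector(r0), config$nonneg_floor)
        x <- emu_from_parts()
      } else {
        ok <- den > 0
        x[ok] <- pmax(x[ok] * num[ok] / den[ok], config$nonneg_floor)
      }
    }
    means <- tracked_means()
    ll <- if (config$convergence_log) {
      sp <- scatter_projection(ctx, emu_vol(x), scat)
      yh <- forward_emulated(ctx, x) + sp
      sum(ifelse(y > 0, y * log(pmax(yh, .Machine$double.xmin)), 0)) - sum(yh)
    } else NA_real_
    chg <- if (is.null(prev_means)) NA_real_
           else max(abs(means - prev_means) / pmax(abs(prev_means), 1e-300))
    prev_means <- means
    conv[[it]] <- data.frame(iteration = it, max_rel_change = chg,
                             log_likelihood = ll)
    if (rv) {
      est_log[[it]] <- data.frame(label = labs, name = region_names,
                                  volume_ml = vol_counts * fine_vox_ml,
                                  concentration = conc, iteration = it,
                                  stringsAsFactors = FALSE)
    } else if (!is.null(rmap)) {
      est_log[[it]] <- cuv_estimates(it)
    }
  }
  internal <- if (rv) {
    x_int <- numeric(prod(di))
    x_int[labelled] <- conc[match(lab_i[labelled], labs)]
    x_int[!labelled] <- x0_e[e_idx[!labelled]]
    volume_grid(array(x_int, di), vs / fac, emu0$origin)
  } else {
    volume_grid(upsample_to_internal(x, fac), vs / fac, emu0$origin)
  }
  out_sm <- source_model(internal,
                         region_map = source_template$region_map,
                         emulated_factor = fac,
                         mode = source_template$mode)
  list(source = out_sm,
       estimates = if (length(est_log)) do.call(rbind, est_log) else NULL,
       convergence = do.call(rbind, conv))
}

#' Calibration factor from a uniform-phantom reconstruction
#'
#' The reconstructed signal in a large VOI well inside a uniform cylinder
#' is related to the known activity concentration; dividing subsequent
#' reconstructions by `value` yields MBq/mL.
#'
#' @param recon_of_uniform_phantom reconstructed [volume_grid].
#' @param voi binary mask on the same grid (non-empty).
#' @param true_concentration known concentration (MBq/mL, > 0).
#' @return object of class `calibration_factor` with field `value` =
#'   (mean reconstructed VOI value) / (true concentration).
#' @export
calibrate <- function(recon_of_uniform_phantom, voi, true_concentration) {
  stopifnot(inherits(recon_of_uniform_phantom, "volume_grid"))
  voi <- as.array(voi) != 0
  if (!any(voi)) stop("empty VOI")
  if (true_concentration <= 0) stop("true_concentration must be > 0")
  structure(list(value = mean(recon_of_uniform_phantom$data[voi]) /
                   true_concentration,
                 voi_volume_ml = sum(voi) *
                   voxel_volume_ml(recon_of_uniform_phantom)),
            class = "calibration_factor")
}

#' Reconstruct every realization of a bootstrap set
#'
#' Applies [osem()] with identical configuration to each noise
#' realization; downstream summaries take the mean and SD over the
#' returned per-realization estimates.
#'
#' @param set a `noise_realization_set` (see [bootstrap_realizations()]),
#'   or a plain list of [projection_set]s.
#' @inheritParams osem
#' @return list of per-realization estimate data.frames (final iteration),
#'   with the realization index in column `realization`.
#' @export
reconstruct_bootstrap <- function(set, mu = NULL, res = NULL, scat = NULL,
                                  source_template, config = recon_config(),
                                  calibration = 1) {
  reals <- if (inherits(set, "noise_realization_set")) set$realizations
           else set
  lapply(seq_along(reals), function(i) {
    fit <- osem(reals[[i]], mu, res, scat, source_template, config,
                calibration)
    est <- extract_estimates(fit$source, iteration = config$n_iterations)
    est$realization <- i
    est
  })
}
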