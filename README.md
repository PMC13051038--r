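# rvspect

Quantitative SPECT activity quantification with **regional voxels**.

## What this is for

Radionuclide therapy (e.g. [177Lu]Lu-DOTA-TATE/TOC for neuroendocrine
tumors) needs regional mean activity concentrations (MBq/mL) in kidneys,
spleen and tumors for patient-specific dosimetry.  SPECT's limited spatial
resolution biases such regional means — the partial-volume effect (PVE).
`rvspect` implements and compares, over one shared system model, the two
standard ways of injecting the "regions are uniform" prior that PVE
correction needs:

* **cu.v. + RC-PVC** — conventional cuboid-voxel OS-EM reconstruction
  followed by recovery-coefficient partial-volume correction.  Recovery is
  parameterized by the volume-to-surface ratio η and iteration count *n*,

      RC(η, n) = 1 / (1 + α_n · η^(−β_n)),

  fitted by nonlinear least squares to sphere-phantom measurements, and
  applied with spill-in correction

      C_pvc = (C_img − C_bkg · (1 − RC)) / RC .

* **r.v.** — regional voxels: the source basis functions *are* the
  anatomical regions, and OS-EM estimates one concentration per region
  directly from the projections (`x ← x · Aᵀ(y/(Ax+s)) / Aᵀ1`, with the
  back-projected numerator and the sensitivity summed region-wise before
  their quotient).

The shared system model is a rotation-based projector with bilinear
interpolation, CT-derived attenuation, a distance-dependent Gaussian
collimator-detector response, an effective-scatter-source term, and
multi-bed axial offsets; back projection is its exact adjoint.  A fixtures
module generates digital phantoms (including a configurable NEMA-style
six-sphere body phantom), Poisson noise, and list-mode-style bootstrap
realizations, so every claim is testable without patient data.

## Worked example

Simulate a two-region phantom, acquire noisy projections, and estimate
regional concentrations directly from the projections:

```r
library(rvspect)

# 1. a two-region abdomen-like phantom on the fine internal grid
spec <- phantom_spec(
  matrix_shape = c(64, 64, 16), voxel_size = c(2.21, 2.21, 4.42),
  bodies = list(
    list(shape = "sphere",    center = c(-20, 0, 0), radius = 18,
         activity = 1.0, density = 1.0,  label = 2L),
    list(shape = "ellipsoid", center = c(30, 10, 0),
         semiaxes = c(14, 20, 20), activity = 0.5, density = 1.05, label = 3L)),
  background = list(activity = 0.1, density = 1.0, label = 1L))
ph <- make_phantom(spec)

# 2. acquisition: 30 views, 4.42 mm pixels, medium-energy collimator response
geom <- acquisition_geometry(n_views = 30, orbit_radius_mm = 200,
                             pixel_size_mm = c(4.42, 4.42),
                             detector_shape = c(32L, 16L),
                             time_per_view_s = 10)
res  <- resolution_model()
mu   <- density_to_attenuation(downsample_to_emulated(ph$density, c(2, 2, 1)))

# 3. simulate counts and add Poisson noise
truth <- source_model(ph$activity, ph$region_map,
                      emulated_factor = c(2, 2, 1), mode = "rv")
clean <- forward_project(truth, mu, geom, res, calibration = 10)
noisy <- add_poisson_noise(clean, seed = 42)

# 4. regional-voxel OS-EM: one concentration per region, 8 it x 10 subsets
tmpl <- source_model(volume_grid(array(1, dim(ph$activity$data)),
                                 ph$activity$voxel_size),
                     ph$region_map, c(2, 2, 1), "rv")
fit  <- osem(noisy, mu, res, NULL, tmpl,
             recon_config(n_iterations = 8, n_subsets = 10),
             calibration = 10)
extract_estimates(fit$source)
```

Output (~200 000 counts over 30 views):

```
  label name volume_ml concentration iteration
1     1    1    1367.2         0.101        NA
2     2    2      24.4         1.018        NA
3     3    3      23.2         0.493        NA
```

The three regional estimates (0.101, 1.018, 0.493 MBq/mL) recover the
simulated truth (0.1, 1.0, 0.5 MBq/mL) to within ~2% despite the ~17 mm
system FWHM, because the regional basis removes the partial-volume bias
that a VOI mean over a voxel image would suffer; run
`compare_methods_report()` to reproduce the full three-way comparison
(r.v. vs cu.v.+PVC vs cu.v.) with per-structure mean ± SD errors over
noise realizations, and `misalignment_experiment()` for the sensitivity of
each method to SPECT/CT misregistration.

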