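---
title: "Quantifying activity concentration with regional voxels: models and methods"
author: "rvspect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying activity concentration with regional voxels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The estimation problem

Quantitative SPECT for radionuclide-therapy dosimetry (for instance
[177Lu]Lu-DOTA-TATE/TOC therapy of neuroendocrine tumors) needs regional
mean activity concentrations in MBq/mL for kidneys, spleen and tumors.
The gamma camera's distance-dependent spatial resolution (15--20 mm FWHM
at typical orbit radii with a medium-energy collimator) makes regional
means from a reconstructed image biased --- the partial-volume effect
(PVE).  Resolution modelling in the reconstruction cannot remove the bias
completely, because the projection operator has a null space: components
of the source distribution are simply not measurable, and can only be
restored from prior information.  The usual prior is that an anatomical
region has uniform concentration.  That prior can enter in two places:

* **after** reconstruction, as a recovery-coefficient (RC) correction of
  VOI means measured on a conventional cuboid-voxel (cu.v.) image; or
* **inside** the estimation, by using the regions themselves as the source
  basis functions ("regional voxels", r.v.), so that the algorithm
  estimates one concentration per region directly from the projections.

`rvspect` implements both routes over one shared system model so they can
be compared like-for-like, together with the synthetic phantoms and noise
machinery needed to evaluate them without patient data.

## System model

The projector is rotation-based with bilinear interpolation: for every
view the source and attenuation volumes are rotated so the detector lies
along +y of the rotated frame, each (x, z) plane is attenuated and
convolved with the collimator-detector response kernel for its distance,
and the planes are summed toward the detector.  Conventions are fixed and
documented in `?projector`: rotation centre at the matrix centre, planes
behind the rotation axis use a larger PSF distance
(`orbit_radius - plane offset`), and the attenuation factor of a plane is
`exp(-dy * (mu summed over the planes nearer the detector + half of the
plane itself))`.  One detector pixel then accumulates
`calibration * time * voxel volume * sum of planes`, so with attenuation
and resolution modelling disabled a view conserves
`total activity x time x calibration` (verified to < 1% for sources inside
the transaxial field of view; the bilinear rotation redistributes single
voxels by a few percent but conserves extended sources much more tightly).

Key modelling choices:

* **Collimator response.** A Gaussian whose FWHM follows the geometric
  collimator model, `FWHM(d) = sqrt(intrinsic^2 + (D (L + d) / L)^2)` with
  hole diameter `D` and effective hole length `L`.  Defaults
  (`D = 3 mm`, `L = 55 mm`, intrinsic 3.9 mm) approximate a medium-energy
  collimator with a 5/8-inch crystal at 208 keV, giving ~16.6 mm FWHM at
  250 mm.  Kernels are truncated at 4 sigma and renormalized so counts are
  conserved.  Inside the projector, kernel distances are quantized to
  10 mm steps (`kernel_distance_step_mm`), so neighbouring planes share a
  kernel; across one step the FWHM changes by well under half a
  millimetre, far below any other model error, and the forward/back pair
  stays an exact adjoint because grouped planes share exactly the same
  (symmetric) kernel.
* **Attenuation.** CT numbers map to density by a multi-linear segment
  table anchored at air (-1000 HU, 0 g/cm3) and water (0 HU, 1 g/cm3);
  density maps to the linear attenuation coefficient by a soft-tissue /
  bone threshold (default 1.15 g/cm3) and per-material mass attenuation
  coefficients at 208 keV (0.136 / 0.146 cm2/g).
* **Scatter.** An effective-scatter-source model: the activity is
  convolved with a normalized isotropic mono-exponential kernel
  (default decay 30 mm) and scaled by an amplitude (default 0.2,
  a typical scatter-to-primary ratio for the 177Lu photopeak window); the
  result is projected and added to the primary term.  A flag
  (`mean_scatter_energy_mode`) projects the scatter source through an
  attenuation map rescaled voxel-wise by a simple two-energy weighting to
  reflect the lower mean energy of scattered photons; this weighting is a
  deliberate, simple approximation and is **not validated** --- the default
  uses the photopeak map.
* **Multi-bed acquisitions** project the source to each axial bed position
  separately (a sparse 1-D linear-interpolation shift), and back-project
  through the transposed shift.

Back projection is built from the transposes of the same sparse rotation
and shift operators and the same symmetric kernels, so
`<Ax, y> = <x, At y>` holds to machine precision for every combination of
attenuation, resolution and bed settings --- the property OS-EM's
convergence relies on, and the first thing the test suite checks.

## Source representations

A `source_model` stores the distribution on a fine *internal* grid
(default 1.105 x 1.105 x 4.42 mm3, the grid of the region map) but behaves
toward the projector as an image at a coarser *emulated* voxel size, an
exact integer multiple (default factor 4 x 4 x 1, i.e. 4.42 mm cubes
matching the detector pixels).  Down-sampling block-averages and
up-sampling partitions, so both conserve total activity exactly; a finer
projector grid would add cost without adding projection accuracy.

In r.v. mode a `region_map` labels every internal voxel with its region;
the background is itself a region, and a configurable number of first/last
transversal slices can be left unlabelled (label 0) so that zero-count
projection rows from a detector smaller than the matrix do not contaminate
the background estimate (the historical convention is 25 slices at each
end of a 128-slice matrix).  Label-0 voxels update voxel-wise at the
emulated size, which is also how unlabelled space can be partitioned into
cuboid regions in mixed descriptions.

## OS-EM over both representations

The estimation engine is ordered-subsets EM with the standard
multiplicative update `x <- x * At(y / (Ax + s)) / At(1)`, views assigned
to subsets round-robin with stride `n_subsets` (maximal angular
separation; ten subsets by default), uniform positive initialization, and
the scatter estimate `s` recomputed from the current image each subset and
held fixed in the denominator (added, never deconvolved).  Where the
expected count is zero the data are zero too and the ratio is taken as
zero; voxels with zero sensitivity are frozen.

For regional voxels, both the back-projected ratio and the sensitivity are
partitioned onto the internal grid and **summed within each region before
taking their quotient**.  This is the maximum-likelihood update for region
basis functions: averaging only the ratio image would weight all voxels of
a region equally regardless of how much each contributes to the data, and
would not have the true concentrations as a fixed point.  With the
quotient-of-sums update, projecting a region-wise-constant phantom through
the same system model and reconstructing with the true region map returns
every regional concentration to within 0.5% after 8 iterations x 10
subsets (the deliberate "inverse crime" self-consistency check in the
test suite).  Whether the original formulation weighted its regional
average by sensitivity is an assumption we record; the quotient-of-sums
form is the one with the correct fixed point.

Regional estimates stabilize far earlier than cuboid-voxel images: with
the default models, successive-iteration changes of regional means fall
below 0.5% within a few iterations for r.v., while cu.v. VOI means keep
drifting toward 40 iterations, which is why the defaults are 8 x 10 for
r.v. and 40 x 10 for cu.v. (both exposed in `recon_config`).

## Recovery-coefficient PVC

For cu.v. images the package implements the standard post-reconstruction
correction.  The recovery coefficient is parameterized by the
volume-to-surface ratio `eta = V/S` (a shape descriptor; `r/3` for a
sphere) and the iteration count `n`:

    RC(eta, n) = 1 / (1 + alpha_n * eta^(-beta_n))

fitted by bounded nonlinear least squares (`minpack.lm`), with the
exponent sign chosen so recovery grows with `eta` and tends to 1 for large
objects.  The correction inverts the linear mixing model

    C_img = RC * C_true + (1 - RC) * C_bkg,

with the background concentration sampled in a shell built as the logical
difference of two successive 6-connected dilations of the object VOI
(defaults inner 1, outer 3 voxels, applied at the emulated voxel size in
the evaluation drivers so the shell sits a physically sensible 4--13 mm
from the object; the radii are an assumption and configurable).

`eta` needs a surface area.  The default renders a marching-tetrahedra
iso-surface at level 0.5 over a lightly box-smoothed copy of the mask;
the smoothing removes the staircase bias that makes meshes over raw binary
masks overestimate curved surfaces by ~20%, at the price of slightly
rounding sharp edges (a digital 44.2 mm cube measures ~4% high in `eta` at
1.105 mm voxels; a 30 mm sphere is within 1%).  Voxel-face counting is
kept as a diagnostic alternative; it is exact for axis-aligned boxes and
~1.5x high for spheres.

A practical caveat the synthetic experiments expose: when the fitted curve
is applied back to sphere-like objects, the two-parameter family cannot
follow the measured (eta, RC) points exactly, and its structured residuals
(about +-10% across the 1--113 mL volume range) translate directly into
over- or under-correction for individual spheres.  For anatomically shaped
organs the sphere-derived curve systematically under-corrects, which is
the regime where regional voxels show their largest advantage.

## Synthetic phantoms and noise

`make_phantom` rasterizes geometric primitives by the voxel-centre test
(no anti-aliasing), so the activity map and the region map agree exactly
-- the assumption underlying r.v.  Digitization makes a primitive's volume
oscillate around the analytic value (up to ~8% for organ-scale spheres at
4.42 mm voxels, converging as voxels shrink); regional truth is therefore
always taken as the mean over the digital region, not the analytic value.
Two ready-made phantoms cover the main experiments: a NEMA-style
six-sphere body phantom whose default volumes span 1.2--113.1 mL
(diameters 13.2--60 mm, spheres on a 57.2 mm ring in an elliptic torso),
and an organ-scale abdomen (two ~145 mL kidneys, a ~200 mL spleen, an
8 mL tumor).  In both, the air surrounding the torso is labelled as its
own nuisance region (named "air") rather than left unlabelled: the truth
is then region-wise constant over the whole field of view, which is the
premise of the regional-voxel self-consistency checks, and the evaluation
drivers exclude it from structure statistics.  Regional estimates for
organ-scale regions stabilize within a handful of iterations; a 1.2 mL
sphere in a warm background still moves by ~1% per iteration at the
eighth, so small-volume estimates should be read with the iteration count
in mind.  Default acquisition settings mirror a common 177Lu protocol:
60 views over 360 degrees, 4.42 mm detector pixels, 45 s per view, and a
system sensitivity of 10 cps/MBq, which yields realistic view totals of
~10^5 counts.

Noise comes in two forms.  `add_poisson_noise` draws each pixel
independently with the expected count as mean.  `bootstrap_realizations`
emulates list-mode bootstrapping: each pixel's parent count is split
multinomially into `n_bins` time bins, and a realization redraws `n_bins`
bins with replacement --- one shared draw per realization, since resampled
time bins are global.  The per-pixel variance of this scheme is
`N (1 - 1/n_bins)`, Poisson-like for many bins; note that a single pixel's
*sample* variance across realizations fluctuates substantially because the
bin split is frozen, so variance checks should average over pixels.  Every
function that consumes randomness requires an explicit seed; there is no
silent default.

What the synthetic data do **not** emulate: intra-region uptake
heterogeneity (the r.v. uniformity prior is exactly true here, so r.v.
accuracy on these phantoms is an upper bound), septal penetration and
energy-resolution effects, segmentation error on anatomy (region maps are
exact by construction except where the misalignment experiments shift
them), and anthropomorphic anatomy.  Passing tests therefore demonstrate
the estimators' internal consistency and their relative behaviour under
PVE, noise and misregistration --- not absolute clinical accuracy.

## Evaluation experiments

`compare_methods_report` runs the full three-way comparison (r.v.,
cu.v.+PVC, cu.v. raw) on any phantom: noise-free projection through the
full model, Poisson realizations (realization `i` uses `seed + i`),
estimation by all methods, and relative errors `eps = C_est/C_ref - 1`
against the phantom truth, aggregated as mean +- SD over realizations.
`misalignment_experiment` emulates SPECT/CT misregistration by translating
the density map (linear interpolation) and the region map/VOIs (nearest
neighbour, so labels stay integral) before estimation while the
projections stay fixed; shifting the derived maps is equivalent to
shifting the CT before segmentation for a rigid translation.  Structures
whose centroid falls within a configurable margin (default 2 cm) of the
transaxial FOV edge can be excluded via `peripheral_labels`.

Problem sizes for the shipped experiments were chosen once: emulated
matrices of 64 x 64 x 64 at 4.42 mm (internal 256 x 256 x 64 at
1.105 x 1.105 x 4.42 mm3), 60 views, 10 noise realizations for the method
comparison and a {0, +-4, +-10} mm offset grid for the misalignment sweep
--- large enough for the effects under study (PVE spans a factor ~3 in
recovery across the sphere set; misalignment effects reach tens of
percent) while keeping a full run on a single CPU in the tens of minutes.

On these conditions the experiments reproduce the expected qualitative
picture: r.v. mean errors within a few percent for all structures;
cu.v.+PVC intermediate; cu.v. raw strongly negative and worsening
monotonically with misalignment, while r.v. drifts both up and down by
only a few percent because the estimated concentration follows the
(shifted) region definition rather than losing counts at the VOI boundary.

## Numerical choices and edge cases

* Rotation/shift operators are exact sparse matrices; adjointness is by
  construction, not by numerical coincidence.
* Kernels: odd length, symmetric, renormalized after truncation.
* EM guards: `0/0 := 0` ratios, frozen zero-sensitivity voxels, a small
  positive floor (`1e-12`) instead of hard zeros so multiplicative updates
  can recover.
* Down/up-sampling require exact divisibility (no padding); a mismatch is
  an error rather than a silent crop.
* The RC fit restarts from three initial points and reports residuals;
  data RC values above 1.2 are rejected as input errors, while the model
  itself is clamped to (0, 1].
* Empty regions, empty VOIs, empty background shells, non-integer
  bootstrap inputs and missing seeds all raise immediate errors.

## Known limitations

* The Metz-style geometric response is approximated by its Gaussian
  envelope; the exact aperture transfer function is not implemented.
* The mean-scatter-energy variant is a placeholder approximation (see
  above) and off by default.
* The projector assumes square in-plane voxels equal to the detector
  pixel size at the emulated resolution.
* Bootstrap emulation resamples a single noisy parent, reproducing the
  statistical structure of list-mode bootstrapping but inheriting the
  parent's particular noise realization as its mean.
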