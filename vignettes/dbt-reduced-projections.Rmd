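---
title: "Evaluating reduced-projection DBT reconstruction with DBTrecon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating reduced-projection DBT reconstruction with DBTrecon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the package addresses

Digital breast tomosynthesis (DBT) reconstructs a quasi-3D breast volume
from a handful of low-dose projection views acquired over a very narrow arc
(here 15 views over 15 degrees).  Because each view adds dose, an obvious
dose-reduction strategy is to *thin* the acquisition — keep only every other
view, turning a 15-view scan into a 7-view one at roughly half the total
exposure.  The question is which reconstruction algorithm best preserves
image quality, and in particular lesion contrast, when half the data are
discarded.

`DBTrecon` frames this as a fully synthetic, reproducible experiment: it
generates a heterogeneous digital breast phantom with known inserts,
simulates the noisy limited-angle acquisition, reconstructs with four
algorithms — filtered back projection (FBP, Ramp and Shepp–Logan kernels),
SART, MLEM, and the total-variation-minimizing ASD-POCS — and quantifies
spatial resolution (FWHM), low-contrast detectability (CNR) and structural
preservation (SSIM/MSSIM) in the in-focus plane at both view counts.

## Acquisition model

The scanner model is monoenergetic Beer–Lambert with Poisson quantum noise
and an ideal detector:

* The X-ray source moves along a partial-isocentric arc about a pivot on the
  breast-support plane; the flat detector is stationary in the `z = 0`
  plane.  View angles are evenly spaced over `[-arc/2, +arc/2]`, endpoints
  included, so the 15-view, 15-degree default samples −7.5° … +7.5° in steps
  of 15/14°.
* Geometry constants are not physical measurements of any particular
  scanner; the defaults (700 mm source–detector, 660 mm source–support,
  0.14 mm binned pixel pitch, stationary detector) are representative of a
  commercial unit and fully config-overridable (`geometryConfig()`).
* Each detector pixel records the line integral of linear attenuation along
  the ray from the view's source position through the pixel center
  (`forwardProject()`).  With quantum noise enabled, the detected count is
  `N ~ Poisson(fluence · exp(−p))` and the recorded value is
  `−ln(max(N, 1)/fluence)`; flooring counts at one keeps the log finite at
  very low exposure and is part of the documented contract so results are
  bit-reproducible.
* The default fluence is `1e4` photons/pixel/view.  Through a 4-cm 50/50
  breast (line integrals around 2) this leaves roughly 1.3 × 10³ detected
  photons per pixel, i.e. relative noise of a few percent on the line
  integrals — a realistic screening-DBT regime.  The value was fixed once as
  part of the study design.

Projection thinning (`thinProjections()`) keeps the views at odd 0-based
indices 1, 3, …, n−2.  For 15 views this is the only equal-stride selection
of exactly seven views that stays symmetric about the central angle; it
drops both endpoint views, mildly narrowing the effective arc (to 6/7 of
the original).  Thinning is a pure selection of already-acquired images —
nothing is re-simulated — which is precisely the half-dose scenario being
studied.

## Projectors

Two ray models implement the system operator:

* **Joseph-style** (default): slice-driven bilinear interpolation, weighted
  by the oblique path length through each slice.  Smooth in the volume
  coefficients, which iterative algorithms need.
* **Siddon-style**: exact voxel-intersection chord lengths.  Slower, used as
  the independently checkable alternative; the test suite also rebuilds both
  operators as explicit dense matrices in plain R and compares.

Forward and backward passes apply identical weights, so they form an exact
adjoint pair (verified to ~1e-15 relative; the contract requires 1e-6).
Rays that miss the volume contribute exactly zero — the standard silent
truncation contract for limited-angle geometries, where partial coverage is
guaranteed.  Indexing is 0-based internally with voxel/pixel centers at
half-integer offsets; the volume's first axis is the tube-motion axis.

## Phantom generator

`phantomSpec()`/`buildPhantom()` emulate a BR3D-style heterogeneous slab:

* **Background**: band-limited Gaussian noise (correlation length 2.5 mm)
  thresholded at the requested mean glandular fraction (default 0.5) into a
  two-phase adipose/glandular medium, then lightly smoothed.  Values always
  stay within `[attenuation_adipose, attenuation_glandular]` = [0.046,
  0.080] mm⁻¹, nominal monoenergetic values around 20 keV effective energy.
  The real phantom's swirled epoxy pattern is not modeled beyond its
  two-phase 50/50 composition and smooth spatial correlation.
* **Inserts**: spheres rasterized with partial-volume weights from 6×6×12
  subvoxel sampling, so the 0.29-mm microcalcification — smaller than a
  voxel — still perturbs the image the way a physical MC perturbs the FWHM
  measurement.  MCs (0.29, 0.40 mm, CaCO₃-like, 0.50 mm⁻¹) *replace* the
  local background; masses (3.9, 4.7 mm, epoxy-like) *add* +0.015 mm⁻¹ to
  it.  A ground-truth registry records every insert's center and diameter.
* **Field of view**: the physical target slab is 40 mm thick and laterally
  much wider; the modeled volume is a 17.92 × 17.92 × 32 mm region (128 ×
  128 × 32 voxels at 0.14/0.14/1 mm) around the insert cluster, resting on
  the support plane.  This keeps the standard pixel-unit ROI sizes valid
  at full pitch while keeping a ten-seed study in minutes on one CPU; the
  surrounding slab material outside the field contributes no scatter in
  this model, so cropping loses nothing except lateral truncation effects
  at the volume edge.
* Identical `(spec, seed)` gives bit-identical volumes; the insert registry
  is independent of the texture seed.

What the generator deliberately does **not** emulate: detector blur and lag,
focal-spot size, scatter, beam hardening or any polyenergetic effect, and
electronic noise.  Passing tests therefore demonstrate the *algorithmic*
behavior of the reconstruction chain under quantum noise and view reduction,
not the full physics of a clinical system — see "Known limitations" below
for where this matters.

## Reconstruction algorithms

All four algorithms consume the same line-integral data and the same
operator, and all are deterministic mappings of their inputs.

**FBP** filters each view along the detector axis parallel to the tube
motion with a 1D frequency-domain kernel (|f| ramp, or ramp × sinc for
Shepp–Logan), zero-padded to the next power of two, then backprojects and
normalizes by view count.  The filtering is one-dimensional because the
narrow arc provides frequency support essentially only along the motion
axis; a 2D kernel would mostly filter directions the data cannot support.

**SART** sweeps the views in ascending angle order; for each view the full
voxel update uses all rays of that view with the standard row-sum/column-sum
normalizations, relaxation 1.0 (config-overridable, per-iteration schedules
allowed), and optional nonnegativity clamping after each view.  Default 5
iterations.

**MLEM** applies the multiplicative update `x ← x · Aᵀ(b/(Ax+ε)) / Aᵀ1` to
the clamped nonnegative line integrals treated as a sinogram.  MLEM's
statistical derivation assumes counts; applying it to log-converted data is
the common tomosynthesis practice modeled here and is stated explicitly for
that reason.  Initialization is the uniform positive volume
`mean(b)/mean(Aᵀ1)` (a multiplicative update cannot leave zero).  Default 2
iterations — MLEM amplifies high-frequency noise with iteration count, so
few iterations favor low-contrast detection.

**ASD-POCS** alternates data-consistency and TV descent per outer iteration:

1. *POCS step*: one SART sweep with relaxation β and positivity.  It is
   implemented as exactly the SART code path (positivity after each view);
   since the positivity projection is idempotent, this satisfies the
   "sweep followed by positivity" structure while making the α → 0 and
   ng = 0 degeneracies *exactly* the SART trajectory rather than
   approximately so.  The image change magnitude `dp` is recorded.
2. *TV step*: `ng` steepest-descent substeps of fixed size `dtvg = α·dp`
   along the unit-normalized gradient of the δ-smoothed TV functional
   (δ = 1e-8 guards the norm at zero gradient); the total TV-step magnitude
   `dg` is recorded.
3. *Adaptation*: β ← β·β_red each iteration; α ← α·α_red whenever
   `dg > γ_max·dp` while the data residual exceeds ε.

Defaults: 5 outer iterations, α = 0.002, ng = 25, β = 1.0, β_red = 0.995,
α_red = 0.95, γ_max = 0.95, ε = 0.  With ε = 0 the α-shrink branch is always
armed; with the default α and ng the TV excursion is only 5% of the POCS
step (`dg ≈ ng·α·dp = 0.05·dp`), so α in practice never shrinks — a gentle,
contrast-preserving amount of TV smoothing per iteration.  One final
positivity projection closes the run so the returned volume is nonnegative
even after the last TV descent.  Residual and TV histories are recorded
every iteration.

Total variation is the sum over voxels of the Euclidean norm of the
forward-difference gradient, one-sided at boundaries; its value is computed
unsmoothed, the descent gradient from the δ-smoothed functional.

## Metrics

* **FWHM** (`profileFWHM()`): three parallel single-pixel profiles through
  an MC along the in-plane axis perpendicular to the tube sweep (center
  line plus ±1 pixel neighbors along the sweep axis).  Background is the
  mean of the outer 20% of samples at each end; the half maximum is
  background-relative, crossings linearly interpolated.  The
  background-relative definition makes the measure invariant to intensity
  scale and offset, which matters because FBP output is on an arbitrary
  linear scale.  The three lines are averaged; failures (no interior peak,
  unbracketed half maximum) are flagged, never silently zeroed.
* **CNR** = (μ_feature − μ_bg)/σ_bg with sample-SD σ_bg.  Feature ROIs are
  defined by physical size — 2.94 × 2.94 mm for the 3.9-mm mass and 4.62 ×
  3.50 mm for the 4.7-mm mass, which at 0.14-mm pitch are exactly 21 × 21
  and 33 × 25 pixels.  The background ROI has the same shape and sits at a
  registry-recorded lesion-free location in the same slice.
* **SSIM/MSSIM** (`ssim()`): luminance × contrast × structure per local
  window with unit exponents, 11 × 11 Gaussian taper (σ = 1.5 px),
  K1 = 0.01, K2 = 0.03, C3 = C2/2, dynamic range = max − min of the
  reference; the map is averaged over all fully-interior windows.  In the
  thinning comparison the 15-view reconstruction of the in-focus plane is
  the reference and the 7-view one the objective, so MSSIM rows exist only
  for the 7-view arm.
* **RMSE / QI**: consecutive-iterate RMSE and the universal image quality
  index (the C1 = C2 = 0 specialization of SSIM, 8 × 8 uniform window,
  zero-variance windows skipped and counted) drive the iteration-count
  selection study.
* **Rate of change** = 100 · (value₇ − value₁₅)/value₁₅, percent.

## Experiment drivers

* `runParameterSweep()` grids (α, ng) for ASD-POCS and records FWHM, CNR and
  background SD per seed — the design that justifies α = 0.002, ng = 25.
  Raising α monotonically flattens the background (lower σ_bg) at the price
  of resolution.
* `runConvergenceStudy()` records consecutive-iterate RMSE and QI for SART,
  MLEM and ASD-POCS — the procedure behind the 5/5/2 iteration defaults.
* `runProjectionComparison()` is the headline study: per seed, one 15-view
  noisy acquisition, a thinned 7-view copy, all five algorithm variants at
  both view counts, all metrics, plus MSSIM(7 vs 15); summaries report
  across-seed means and standard errors.  The physical experiment measured
  one phantom; the synthetic study runs 10 seeds (default `seeds = 0:9`)
  because its acceptance must be statistical.  Acquisition noise seeds are
  derived deterministically from the phantom seed (seed + 5000), so the
  whole report is bit-reproducible from the config alone.

The in-focus plane is the slice containing the registered insert centers —
the physical "in-focus plane" of a real phantom measurement, located here
via the ground-truth registry.

## Numerical choices, in one place

* ε-guards: 1e-8 on SART row/column sums and MLEM denominators; TV-gradient
  smoothing δ = 1e-8.  The guards are part of the algorithm contract and are
  mirrored verbatim by the matrix-form test oracles.
* View sweep order: ascending angle, fixed for bit-reproducibility.
* FBP padding: next power of two ≥ twice the detector columns, avoiding
  circular-convolution wrap.
* FWHM background window: outer 20% of samples at each end of the profile.
* Degenerate inputs: σ_bg = 0 yields a flagged undefined CNR; profiles
  without a bracketed interior peak are flagged; QI windows with zero
  variance are skipped with a recorded count; `ng = 0` is a valid ASD-POCS
  configuration (POCS-only).
* TIFF export quantizes to 32-bit levels of the data range with min/max in
  a YAML sidecar (~2e-10 of range round-trip error); the environment's TIFF
  layer does not preserve raw IEEE floats.

## Known limitations

* No detector PSF, focal-spot blur, scatter or polyenergetic physics: the
  simulated system is sharper than a physical one, and simulation and
  reconstruction share the same grid and projector.  Resolution-ordering
  results (which algorithm attains the smallest FWHM) are the quantity most
  sensitive to this: iterative algorithms can partially invert the
  projector's interpolation blur in a way they cannot invert a physical
  detector PSF, and the FWHM profiles run perpendicular to the tube sweep —
  the direction in which FBP's 1D filter adds no sharpening.  Contrast- and
  structure-based orderings (CNR rate of change, MSSIM) are driven by noise
  propagation and regularization and transfer more robustly.
* Attenuation coefficients are nominal monoenergetic values; the materials,
  not the coefficients, are what the phantom specification fixes.
* Average glandular dose is carried as metadata only; no dosimetry model.
* No observer study: all metrics are physical, not psychophysical.
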