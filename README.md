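# DBTrecon

Simulation and limited-angle iterative reconstruction for digital breast
tomosynthesis (DBT), built to answer one question quantitatively: **how much
image quality survives when a 15-view DBT acquisition is thinned to 7 views
(roughly half the dose), and which reconstruction algorithm preserves lesion
contrast best?**

The package is aimed at medical-imaging researchers and algorithm developers
who want a fully synthetic, bit-reproducible testbed for projection-reduced
DBT: a heterogeneous digital breast phantom with known ground truth, a
narrow-arc acquisition simulator with Poisson quantum noise, four
reconstruction algorithms, and the standard phantom image-quality metrics.

## What it computes

**Forward model.** A monoenergetic Beer–Lambert scanner: the source sweeps a
15° partial-isocentric arc (15 views, −7.5°…+7.5°) above a stationary
detector; each detector pixel records the line integral of attenuation
`p = ∫ μ dl`, and with quantum noise the detected count is
`N ~ Poisson(fluence · e^{−p})`, logged back to `−ln(max(N,1)/fluence)`.
Half-dose acquisitions are produced by *thinning* — keeping the 7 views at
odd indices of the acquired 15-view stack, never re-simulating.

**Phantom.** A BR3D-like slab: band-limited two-phase 50/50
adipose/glandular texture (0.046 / 0.080 mm⁻¹) carrying CaCO₃-like
microcalcifications of 0.29 and 0.40 mm and spheroidal masses of 3.9 and
4.7 mm, rasterized with partial-volume sphere weights on a 128×128×32 grid
(0.14/0.14/1 mm voxels).

**Reconstruction.**

* `fbp()` — filtered back projection, 1D frequency-domain Ramp or
  Shepp–Logan (`|f|·sinc`) kernel along the tube-motion axis;
* `sart()` — simultaneous algebraic reconstruction technique, per-view
  updates with row/column-sum normalization (default 5 iterations);
* `mlem()` — maximum-likelihood expectation maximization, multiplicative
  positive updates (default 2 iterations);
* `asdPocs()` — adaptive steepest descent–projection onto convex sets:
  each outer iteration alternates one SART sweep with positivity (POCS) and
  `ng = 25` total-variation steepest-descent substeps of size
  `α·‖POCS step‖` with `α = 0.002`, with the standard β/α adaptation rules
  (default 5 outer iterations).

**Metrics.** Line-profile FWHM through each microcalcification (three
neighboring profiles perpendicular to the sweep, background-relative half
maximum), CNR `(μ_feature − μ_bg)/σ_bg` with 21×21 px (3.9 mm) and 33×25 px
(4.7 mm) ROIs at 0.14-mm pitch, SSIM/MSSIM (11×11 Gaussian window, unit
exponents, 15-view reconstruction as reference), consecutive-iterate RMSE
and universal quality index (QI), and the 15→7-view rate of change in
percent.

**Experiments.** `runParameterSweep()` (α, ng grids),
`runConvergenceStudy()` (iteration selection via RMSE/QI), and
`runProjectionComparison()` (the headline normal-vs-half study over ten
phantom seeds, reporting means ± standard errors). A thin CLI
(`exec/dbtrecon`, subcommands `phantom simulate reconstruct metrics sweep
converge compare`) wraps the same functions with YAML configs.

## Worked example

Simulate one noisy 15-view acquisition of the default phantom, thin it to 7
views, reconstruct both with ASD-POCS, and measure the thinning cost:

```r
library(DBTrecon)

spec <- phantomSpec(seed = 0)
vol  <- buildPhantom(spec)
op   <- systemOperator(makeGeometry(15, 15), dim(phantomData(vol)),
                       spec@voxel_size)
ps15 <- simulateAcquisition(vol, op, fluence_per_view = 1e4, seed = 5000)
ps7  <- thinProjections(ps15)

rec15 <- asdPocs(ps15, op)
op7   <- systemOperator(ps7@geometry, op@volume_shape, op@voxel_size)
rec7  <- asdPocs(ps7, op7)

reg  <- insertRegistry(vol)
mc   <- reg[reg$id == "mc_040", ]
mass <- reg[reg$id == "mass_390", ]
f15 <- profileFWHM(rec15, c(mc$ix, mc$iy, mc$iz),
                   voxel_size = spec@voxel_size)$fwhm
f7  <- profileFWHM(rec7,  c(mc$ix, mc$iy, mc$iz),
                   voxel_size = spec@voxel_size)$fwhm
sz   <- featureRoiPx(mass$diameter_mm, spec@voxel_size[1])
froi <- roiAround(c(mass$ix, mass$iy), sz, mass$iz)
broi <- roiAround(c(64, 64), sz, mass$iz)      # lesion-free center
c15 <- cnr(rec15, froi, broi)$cnr
c7  <- cnr(rec7,  froi, broi)$cnr
m   <- ssim(reconData(rec15)[, , mc$iz], reconData(rec7)[, , mc$iz])@mssim
```

Output:

```
FWHM  0.40-mm MC : 0.319 mm (15 views) -> 0.352 mm (7 views), change +10.4%
CNR   3.9-mm mass: 0.138 (15 views) -> 0.151 (7 views), change +9.8%
MSSIM 7-vs-15 in-focus plane: 0.784
```

Read: thinning costs ASD-POCS about 10% in microcalcification FWHM (spatial
resolution degrades — TV smoothing plus fewer views), while the 3.9-mm mass
CNR holds up (here it even rises slightly, because the TV penalty suppresses
the extra quantum noise of the half acquisition) and the in-focus plane
stays structurally similar to the full-dose reconstruction (MSSIM 0.78; the
same comparison for ramp-kernel FBP gives a lower value — see the
comparison study). That is the dose-reduction argument the package exists
to quantify.

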