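# Small, fast geometries / phantoms shared across the test files.

tinyGeometry <- function(n_views = 5L, arc = 15, rows = 10L, cols = 10L,
                         pitch = 1.2) {
  makeGeometry(n_views, arc,
               geometryConfig(source_to_detector = 100, source_to_support = 80,
                              detector_rows = rows, detector_cols = cols,
                              pixel_pitch = pitch))
}

tinyOperator <- function(n_views = 5L, shape = c(8L, 8L, 8L),
                         voxel = c(1, 1, 1),
                         interpolation = "joseph", ...) {
  systemOperator(tinyGeometry(n_views, ...), shape, voxel, interpolation)
}

# Noiseless projection set wrapping a bare array.
asProjectionSet <- function(data, geometry) {
  new("ProjectionSet", data = data, geometry = geometry,
      per_view_fluence = NA_real_, noise_seed = NA_integer_)
}

# Down-scaled study configuration: 44 x 44 x 8 voxels at 0.28/0.28/2 mm with
# all four default insert diameters, small detector.  Same physics, minutes
# faster than the full desk-scale setup.
smallPhantomSpec <- function(seed = 0L) {
  phantomSpec(
    volume_extent = c(12.32, 12.32, 16), voxel_size = c(0.28, 0.28, 2),
    mc_inserts = data.frame(x_mm = c(-2.9, 2.9), y_mm = c(-2.9, -2.9),
                            z_mm = 7, diameter_mm = c(0.29, 0.40),
                            attenuation = 0.5),
    mass_inserts = data.frame(x_mm = c(-2.9, 2.9), y_mm = c(2.9, 2.9),
                              z_mm = 7, diameter_mm = c(3.9, 4.7),
                              attenuation = 0.015),
    bg_reference = c(0, -1.5), seed = seed)
}

smallExperimentConfig <- function(seeds = 0L, ...) {
  experimentConfig(
    phantom = smallPhantomSpec(),
    geometry = geometryConfig(detector_rows = 56L, detector_cols = 112L,
                              pixel_pitch = 0.28),
    seeds = seeds, ...)
}

# The per-iteration relaxation sequence ASD-POCS applies, built by the same
# sequential multiplications (cumprod is not bitwise identical).
betaSchedule <- function(beta, beta_red, n) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- beta
    beta <- beta * beta_red
  }
  out
}

# Noisy small-scale acquisition plus its operator.
smallAcquisition <- function(seed = 0L, fluence = 1e4) {
  cfg <- smallExperimentConfig(seeds = seed, fluence_per_view = fluence)
  op <- DBTrecon:::.opForConfig(cfg)
  sim <- DBTrecon:::.simulateForSeed(cfg, seed, op)
  list(config = cfg, op = op, volume = sim$volume, ps = sim$ps15)
}
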