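# Run code under a fixed RNG seed without disturbing the caller's RNG state.
withSeed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Periodic 3D Gaussian low-pass filter (FFT-based); sigma in mm per axis.
.gaussSmooth3d <- function(x, sigma_mm, voxel_size) {
  d <- dim(x)
  H <- 1
  for (a in 1:3) {
    f <- c(0:(d[a] %/% 2), -((d[a] - 1) %/% 2):-1)[1:d[a]] / (d[a] * voxel_size[a])
    h <- exp(-2 * pi^2 * sigma_mm[a]^2 * f^2)
    sh <- c(1, 1, 1); sh[a] <- d[a]
    H <- H * array(rep(h, each = prod(sh[seq_len(a - 1)])), dim = d)
  }
  Re(fft(fft(x) * H, inverse = TRUE)) / prod(d)
}

.defaultMcInserts <- function() {
  data.frame(x_mm = c(-4.27, 4.27), y_mm = c(-4.27, -4.27), z_mm = c(15.5, 15.5),
             diameter_mm = c(0.29, 0.40), attenuation = c(0.50, 0.50))
}

.defaultMassInserts <- function() {
  data.frame(x_mm = c(-4.55, 4.55), y_mm = c(4.55, 4.55), z_mm = c(15.5, 15.5),
             diameter_mm = c(3.9, 4.7), attenuation = c(0.015, 0.015))
}

#' Specify a BR3D-like digital breast phantom
#'
#' The default spec models the central 32 mm of a 40-mm heterogeneous slab of
#' 50/50 glandular/adipose-equivalent material on a 128 x 128 x 32 grid
#' (0.14 x 0.14 x 1 mm voxels), carrying one CaCO3-like microcalcification of
#' each diameter (0.29 and 0.40 mm) and one spheroidal mass of each diameter
#' (3.9 and 4.7 mm), all centered in the mid slice.  Mass attenuation is an
#' additive offset above the local background; MC attenuation is absolute.
#' Monoenergetic (about 20 keV effective) attenuation defaults: adipose
#' 0.046, glandular 0.080, CaCO3 0.50 mm^-1, mass offset +0.015 mm^-1.
#'
#' @param slab_thickness physical slab thickness, mm (metadata).
#' @param volume_extent modeled extents (x, y, z), mm.
#' @param voxel_size voxel sizes (dx, dy, dz), mm.
#' @param background_texture list(correlation_length, glandular_fraction).
#' @param mc_inserts,mass_inserts insert tables (see
#'   \linkS4class{PhantomSpec}); pass \code{data.frame()} for none.
#' @param attenuation_adipose,attenuation_glandular phase attenuations, mm^-1.
#' @param bg_reference lesion-free (x, y) mm for background ROIs.
#' @param seed texture seed.
#' @return a \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(slab_thickness = 40,
                        volume_extent = c(17.92, 17.92, 32),
                        voxel_size = c(0.14, 0.14, 1),
                        background_texture = list(correlation_length = 2.5,
                                                  glandular_fraction = 0.5),
                        mc_inserts = .defaultMcInserts(),
                        mass_inserts = .defaultMassInserts(),
                        attenuation_adipose = 0.046,
                        attenuation_glandular = 0.080,
                        bg_reference = c(0, 0),
                        seed = 0L) {
  new("PhantomSpec",
      slab_thickness = slab_thickness,
      volume_extent = as.numeric(volume_extent),
      voxel_size = as.numeric(voxel_size),
      background_texture = background_texture,
      mc_inserts = as.data.frame(mc_inserts),
      mass_inserts = as.data.frame(mass_inserts),
      attenuation_adipose = attenuation_adipose,
      attenuation_glandular = attenuation_glandular,
      bg_reference = as.numeric(bg_reference),
      seed = as.integer(seed))
}

# Volume fraction of each voxel covered by a sphere, via subvoxel sampling.
# Returns a list(ix, iy, iz ranges, frac array).  Sub-voxel spheres are
# captured through partial-volume weights.
.sphereFractions <- function(dims, voxel_size, center_mm, diameter_mm,
                             nsub = c(6L, 6L, 12L)) {
  r <- diameter_mm / 2
  lo <- pmax(1L, floor((center_mm - r) / voxel_size) + 1L)
  hi <- pmin(dims, ceiling((center_mm + r) / voxel_size))
  idx <- lapply(1:3, function(a) lo[a]:hi[a])
  nb <- vapply(idx, length, 1L)
  frac <- array(0, dim = nb)
  off <- lapply(1:3, function(a) ((seq_len(nsub[a]) - 0.5) / nsub[a]))
  for (ii in seq_len(nb[1])) for (jj in seq_len(nb[2])) for (kk in seq_len(nb[3])) {
    v0 <- (c(idx[[1]][ii], idx[[2]][jj], idx[[3]][kk]) - 1L) * voxel_size
    xs <- v0[1] + off[[1]] * voxel_size[1] - center_mm[1]
    ys <- v0[2] + off[[2]] * voxel_size[2] - center_mm[2]
    zs <- v0[3] + off[[3]] * voxel_size[3] - center_mm[3]
    d2 <- outer(outer(xs^2, ys^2, `+`), zs^2, `+`)
    frac[ii, jj, kk] <- mean(d2 <= r^2)
  }
  list(idx = idx, frac = frac)
}

#' Build a digital phantom volume from its specification
#'
#' The background is band-limited Gaussian noise thresholded into a two-phase
#' adipose/glandular medium at the requested mean glandular fraction, then
#' lightly smoothed, so values stay within
#' \code{[attenuation_adipose, attenuation_glandular]}.  MC inserts replace
#' the background with their absolute attenuation, masses add their offset on
#' top of the local background; both are rasterized with partial-volume
#' sphere weights so sub-voxel MCs still perturb the image.  Identical
#' (spec, seed) yields a bit-identical volume.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return a \linkS4class{PhantomVolume} with a filled insert registry.
#' @examples
#' vol <- buildPhantom(phantomSpec(seed = 1))
#' insertRegistry(vol)
#' @export
buildPhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  vs <- spec@voxel_size
  dims <- as.integer(round(spec@volume_extent / vs))
  bt <- spec@background_texture

  noise <- withSeed(spec@seed, array(rnorm(prod(dims)), dim = dims))
  field <- .gaussSmooth3d(noise, rep(bt$correlation_length / 2, 3), vs)
  gf <- bt$glandular_fraction
  phase <- if (gf <= 0) array(0, dims)
           else if (gf >= 1) array(1, dims)
           else (field > quantile(field, 1 - gf)) * 1
  phase <- .gaussSmooth3d(phase, pmax(vs, 0.2), vs)
  phase <- pmin(pmax(phase, 0), 1)
  mu <- spec@attenuation_adipose +
    phase * (spec@attenuation_glandular - spec@attenuation_adipose)

  # physical coordinates: x, y centered on the volume, z from the slab bottom
  half <- c(spec@volume_extent[1] / 2, spec@volume_extent[2] / 2, 0)
  registry <- data.frame(id = character(0), type = character(0),
                         x_mm = numeric(0), y_mm = numeric(0), z_mm = numeric(0),
                         ix = integer(0), iy = integer(0), iz = integer(0),
                         diameter_mm = numeric(0))
  addInserts <- function(tab, type) {
    for (n in seq_len(nrow(tab))) {
      cen <- c(tab$x_mm[n], tab$y_mm[n], tab$z_mm[n]) + half
      sf <- .sphereFractions(dims, vs, cen, tab$diameter_mm[n])
      ii <- sf$idx[[1]]; jj <- sf$idx[[2]]; kk <- sf$idx[[3]]
      if (type == "mc") {
        mu[ii, jj, kk] <<- mu[ii, jj, kk, drop = FALSE] * (1 - sf$frac) +
          tab$attenuation[n] * sf$frac
      } else {
        mu[ii, jj, kk] <<- mu[ii, jj, kk, drop = FALSE] +
          tab$attenuation[n] * sf$frac
      }
      ivox <- pmin(pmax(ceiling(cen / vs - 1e-9), 1L), dims)
      registry <<- rbind(registry, data.frame(
        id = sprintf("%s_%03.0f", type, tab$diameter_mm[n] * 100),
        type = type, x_mm = tab$x_mm[n], y_mm = tab$y_mm[n], z_mm = tab$z_mm[n],
        ix = ivox[1], iy = ivox[2], iz = ivox[3],
        diameter_mm = tab$diameter_mm[n]))
    }
  }
  addInserts(spec@mc_inserts, "mc")
  addInserts(spec@mass_inserts, "mass")

  new("PhantomVolume", data = mu, voxel_size = vs, insert_registry = registry)
}

setMethod("show", "PhantomVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("PhantomVolume: %d x %d x %d voxels @ %s mm, mu in [%.4f, %.4f] mm^-1\n",
              d[1], d[2], d[3], paste(signif(object@voxel_size, 3), collapse = "/"),
              min(object@data), max(object@data)))
  if (nrow(object@insert_registry))
    cat(sprintf("  %d inserts: %s\n", nrow(object@insert_registry),
                paste(object@insert_registry$id, collapse = ", ")))
  invisible(object)
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %s mm extent @ %s mm voxels, seed %d\n",
              paste(object@volume_extent, collapse = " x "),
              paste(signif(object@voxel_size, 3), collapse = "/"), object@seed))
  cat(sprintf("  %d MC + %d mass inserts, glandular fraction %.2f\n",
              nrow(object@mc_inserts), nrow(object@mass_inserts),
              object@background_texture$glandular_fraction))
  invisible(object)
})
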