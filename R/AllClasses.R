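#' @useDynLib DBTrecon, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats fft mvfft quantile rnorm rpois sd
#' @importFrom utils read.csv write.csv
NULL

.is_increasing <- function(x) all(diff(x) > 0)

#' Acquisition geometry for a narrow-arc tomosynthesis scan
#'
#' Describes the source arc, detector layout and view angles of a digital
#' breast tomosynthesis (DBT) acquisition.  The X-ray tube moves along a
#' partial-isocentric arc about a pivot on the breast-support plane while the
#' detector stays stationary; the view angles are evenly spaced over the arc
#' and symmetric about the central (0 degree) projection.
#'
#' @slot n_views number of projection views.
#' @slot arc_span total angular range of the source arc, degrees.
#' @slot view_angles vector of view angles (degrees), strictly increasing and
#'   symmetric about 0.
#' @slot source_to_detector source-to-detector distance, mm.
#' @slot source_to_support source-to-breast-support distance (equals the
#'   pivot radius of the tube arc), mm.
#' @slot detector_rows,detector_cols detector pixel counts; columns run along
#'   the tube-motion axis, rows perpendicular to it.
#' @slot pixel_pitch detector pixel pitch, mm.
#' @slot detector_motion detector motion mode; only \code{"stationary"} is
#'   supported.
#' @export
setClass("AcquisitionGeometry",
  representation(
    n_views            = "integer",
    arc_span           = "numeric",
    view_angles        = "numeric",
    source_to_detector = "numeric",
    source_to_support  = "numeric",
    detector_rows      = "integer",
    detector_cols      = "integer",
    pixel_pitch        = "numeric",
    detector_motion    = "character"
  ),
  validity = function(object) {
    msg <- character(0)
    if (length(object@view_angles) != object@n_views)
      msg <- c(msg, "view_angles must have exactly n_views entries")
    if (object@n_views > 1L && !.is_increasing(object@view_angles))
      msg <- c(msg, "view_angles must be strictly increasing")
    tol <- 1e-8 * max(1, abs(object@arc_span))
    if (any(abs(object@view_angles + rev(object@view_angles)) > tol))
      msg <- c(msg, "view_angles must be symmetric about 0 degrees")
    if (object@n_views >= 2L) {
      span <- max(object@view_angles) - min(object@view_angles)
      if (abs(span - object@arc_span) > tol)
        msg <- c(msg, "max(view_angles) - min(view_angles) must equal arc_span")
    }
    if (object@source_to_detector <= 0 || object@source_to_support <= 0 ||
        object@pixel_pitch <= 0)
      msg <- c(msg, "all distances and pitches must be strictly positive")
    if (object@source_to_support > object@source_to_detector)
      msg <- c(msg, "source_to_support cannot exceed source_to_detector")
    if (object@detector_rows < 1L || object@detector_cols < 1L)
      msg <- c(msg, "detector dimensions must be positive")
    if (!identical(object@detector_motion, "stationary"))
      msg <- c(msg, "only a stationary detector is supported")
    if (length(msg)) msg else TRUE
  }
)

#' Linear forward/back projection operator
#'
#' Binds an \linkS4class{AcquisitionGeometry} to a reconstruction grid and an
#' interpolation model, defining the system matrix A shared by the simulator
#' and every reconstruction algorithm.  \code{"joseph"} is a voxel-driven
#' bilinear-interpolation projector (smooth, used by default); \code{"siddon"}
#' is an exact voxel-intersection ray tracer.
#'
#' @slot geometry an \linkS4class{AcquisitionGeometry}.
#' @slot volume_shape integer voxel counts (nx, ny, nz); the x axis is the
#'   tube-motion axis, z the slice axis perpendicular to the detector.
#' @slot voxel_size voxel size (dx, dy, dz), mm.
#' @slot volume_origin physical position (mm) of the low corner of the
#'   volume; voxel centers sit at half-integer offsets from it.  The detector
#'   occupies the z = 0 plane.
#' @slot interpolation \code{"joseph"} or \code{"siddon"}.
#' @export
setClass("SystemOperator",
  representation(
    geometry      = "AcquisitionGeometry",
    volume_shape  = "integer",
    voxel_size    = "numeric",
    volume_origin = "numeric",
    interpolation = "character"
  ),
  validity = function(object) {
    msg <- character(0)
    if (length(object@volume_shape) != 3L || any(object@volume_shape < 1L))
      msg <- c(msg, "volume_shape must be three positive voxel counts")
    if (length(object@voxel_size) != 3L || any(object@voxel_size <= 0))
      msg <- c(msg, "voxel_size must be three positive lengths")
    if (length(object@volume_origin) != 3L)
      msg <- c(msg, "volume_origin must have three components")
    if (!object@interpolation %in% c("joseph", "siddon"))
      msg <- c(msg, "interpolation must be 'joseph' or 'siddon'")
    if (length(msg)) msg else TRUE
  }
)

#' Stack of line-integral projection images
#'
#' Log-converted detector data, one image per view: each pixel holds the line
#' integral of linear attenuation (-ln transmission, dimensionless) along the
#' ray from the view's source position through the pixel.
#'
#' @slot data numeric array \code{[col, row, view]}; the first axis is the
#'   detector axis parallel to tube motion.
#' @slot geometry the \linkS4class{AcquisitionGeometry} the stack conforms to.
#' @slot per_view_fluence incident photons per detector pixel per view
#'   (\code{NA} for noiseless data).
#' @slot noise_seed seed used for the Poisson draw (\code{NA} if noiseless).
#' @export
setClass("ProjectionSet",
  representation(
    data             = "array",
    geometry         = "AcquisitionGeometry",
    per_view_fluence = "numeric",
    noise_seed       = "integer"
  ),
  validity = function(object) {
    d <- dim(object@data)
    g <- object@geometry
    msg <- character(0)
    if (length(d) != 3L)
      msg <- c(msg, "data must be a 3D array [col, row, view]")
    else {
      if (d[3] != g@n_views)
        msg <- c(msg, "data view count must equal geometry n_views")
      if (d[1] != g@detector_cols || d[2] != g@detector_rows)
        msg <- c(msg, "data in-plane dimensions must match the detector")
    }
    if (any(!is.finite(object@data)))
      msg <- c(msg, "data must be finite")
    if (length(msg)) msg else TRUE
  }
)

#' Specification of a heterogeneous digital breast phantom
#'
#' Parameterizes a BR3D-like slab: a smoothly swirled two-phase mixture of
#' adipose- and glandular-equivalent material with spherical
#' microcalcification (MC) and mass inserts.  The default spec carries MC
#' diameters 0.29 and 0.40 mm (CaCO3-like) and spheroidal masses of 3.9 and
#' 4.7 mm.
#'
#' @slot slab_thickness physical thickness of the target slab, mm (metadata;
#'   the modeled volume spans \code{volume_extent[3]}).
#' @slot volume_extent modeled extents (x, y, z), mm.
#' @slot voxel_size voxel size (dx, dy, dz), mm.
#' @slot background_texture list with \code{correlation_length} (mm) and
#'   \code{glandular_fraction} (mean glandular volume fraction in [0, 1]).
#' @slot mc_inserts,mass_inserts data.frames with columns \code{x_mm, y_mm,
#'   z_mm, diameter_mm, attenuation} (attenuation: absolute mm^-1 for MCs,
#'   additive offset above local background for masses).
#' @slot attenuation_adipose,attenuation_glandular linear attenuation of the
#'   two background phases, mm^-1.
#' @slot bg_reference (x, y) mm of a lesion-free location used to place
#'   background ROIs (in the insert slice).
#' @slot seed integer seed controlling the background texture.
#' @export
setClass("PhantomSpec",
  representation(
    slab_thickness        = "numeric",
    volume_extent         = "numeric",
    voxel_size            = "numeric",
    background_texture    = "list",
    mc_inserts            = "data.frame",
    mass_inserts          = "data.frame",
    attenuation_adipose   = "numeric",
    attenuation_glandular = "numeric",
    bg_reference          = "numeric",
    seed                  = "integer"
  ),
  validity = function(object) {
    msg <- character(0)
    ext <- object@volume_extent
    if (length(ext) != 3L || any(ext <= 0))
      msg <- c(msg, "volume_extent must be three positive lengths")
    if (length(object@voxel_size) != 3L || any(object@voxel_size <= 0))
      msg <- c(msg, "voxel_size must be three positive lengths")
    bt <- object@background_texture
    if (is.null(bt$correlation_length) || bt$correlation_length <= 0)
      msg <- c(msg, "background_texture$correlation_length must be positive")
    gf <- bt$glandular_fraction
    if (is.null(gf) || gf < 0 || gf > 1)
      msg <- c(msg, "background_texture$glandular_fraction must lie in [0, 1]")
    for (tab in list(mc = object@mc_inserts, mass = object@mass_inserts)) {
      if (nrow(tab) == 0) next
      need <- c("x_mm", "y_mm", "z_mm", "diameter_mm", "attenuation")
      if (!all(need %in% names(tab))) {
        msg <- c(msg, "insert tables need columns x_mm, y_mm, z_mm, diameter_mm, attenuation")
        next
      }
      if (any(tab$diameter_mm <= 0))
        msg <- c(msg, "insert diameters must be positive")
      r <- tab$diameter_mm / 2
      if (any(abs(tab$x_mm) + r > ext[1] / 2 + 1e-9) ||
          any(abs(tab$y_mm) + r > ext[2] / 2 + 1e-9) ||
          any(tab$z_mm - r < -1e-9) || any(tab$z_mm + r > ext[3] + 1e-9))
        msg <- c(msg, "inserts must lie fully inside the volume extent")
    }
    if (object@attenuation_adipose < 0 || object@attenuation_glandular < 0)
      msg <- c(msg, "attenuation coefficients must be nonnegative")
    if (length(msg)) msg else TRUE
  }
)

#' Digital phantom volume
#'
#' A 3D grid of linear attenuation coefficients with a registry of the
#' ground-truth inserts it contains.
#'
#' @slot data numeric array \code{[x, y, z]} of linear attenuation, mm^-1,
#'   all values nonnegative.
#' @slot voxel_size voxel size (dx, dy, dz), mm.
#' @slot insert_registry data.frame with columns \code{id, type, x_mm, y_mm,
#'   z_mm, ix, iy, iz, diameter_mm}; (ix, iy, iz) are 1-based voxel indices
#'   of the insert center.
#' @export
setClass("PhantomVolume",
  representation(
    data            = "array",
    voxel_size      = "numeric",
    insert_registry = "data.frame"
  ),
  validity = function(object) {
    msg <- character(0)
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must be a 3D array")
    if (any(object@data < 0))
      msg <- c(msg, "attenuation values must be nonnegative")
    reg <- object@insert_registry
    if (nrow(reg)) {
      d <- dim(object@data)
      if (any(reg$ix < 1 | reg$ix > d[1] | reg$iy < 1 | reg$iy > d[2] |
              reg$iz < 1 | reg$iz > d[3]))
        msg <- c(msg, "insert_registry centers must map inside the array bounds")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Reconstructed attenuation volume with provenance
#'
#' @slot data numeric array \code{[x, y, z]} (mm^-1 scale for the iterative
#'   algorithms; filtered-backprojection output is on an arbitrary linear
#'   scale).
#' @slot algorithm one of \code{"fbp"}, \code{"sart"}, \code{"mlem"},
#'   \code{"asd_pocs"}.
#' @slot params_used list echoing every parameter the algorithm ran with.
#' @slot residual_history per-iteration data-residual norms ||Ax - b||.
#' @slot tv_history per-iteration total-variation values (ASD-POCS only).
#' @export
setClass("ReconVolume",
  representation(
    data             = "array",
    algorithm        = "character",
    params_used      = "list",
    residual_history = "numeric",
    tv_history       = "numeric"
  ),
  validity = function(object) {
    msg <- character(0)
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must be a 3D array")
    if (!object@algorithm %in% c("fbp", "sart", "mlem", "asd_pocs"))
      msg <- c(msg, "unknown algorithm label")
    if (length(msg)) msg else TRUE
  }
)

# ---- algorithm parameter classes -------------------------------------------

#' Filtered back projection parameters
#' @slot kernel \code{"ramp"} or \code{"shepp_logan"}.
#' @slot filter_axis detector axis the 1D kernel is applied along; only
#'   \code{"motion"} (the tube-motion axis) is supported.
#' @export
setClass("FBPParams",
  representation(kernel = "character", filter_axis = "character"),
  prototype(kernel = "ramp", filter_axis = "motion"),
  validity = function(object) {
    if (!object@kernel %in% c("ramp", "shepp_logan"))
      return("kernel must be 'ramp' or 'shepp_logan'")
    if (!identical(object@filter_axis, "motion"))
      return("only filtering along the tube-motion axis is supported")
    TRUE
  }
)

#' SART parameters
#' @slot n_iterations number of full sweeps over all views (default 5).
#' @slot relaxation relaxation factor in (0, 2); either a scalar or one value
#'   per iteration.
#' @slot nonnegativity clamp negative voxels after each view update.
#' @export
setClass("SARTParams",
  representation(n_iterations = "integer", relaxation = "numeric",
                 nonnegativity = "logical"),
  prototype(n_iterations = 5L, relaxation = 1.0, nonnegativity = TRUE),
  validity = function(object) {
    if (object@n_iterations < 1L) return("n_iterations must be >= 1")
    if (any(object@relaxation <= 0) || any(object@relaxation >= 2))
      return("relaxation must lie in (0, 2)")
    if (!length(object@relaxation) %in% c(1L, object@n_iterations))
      return("relaxation must be scalar or one value per iteration")
    TRUE
  }
)

#' MLEM parameters
#' @slot n_iterations iteration count (default 2).
#' @slot epsilon_guard small positive guard added to denominators.
#' @export
setClass("MLEMParams",
  representation(n_iterations = "integer", epsilon_guard = "numeric"),
  prototype(n_iterations = 2L, epsilon_guard = 1e-8),
  validity = function(object) {
    if (object@n_iterations < 1L) return("n_iterations must be >= 1")
    if (object@epsilon_guard <= 0) return("epsilon_guard must be positive")
    TRUE
  }
)

#' ASD-POCS parameters
#'
#' Adaptive steepest descent-projection onto convex sets: each outer
#' iteration alternates a data-consistency POCS step (one SART sweep with
#' relaxation \code{beta}, positivity enforced) with \code{ng}
#' TV-steepest-descent substeps of size \code{alpha} times the POCS image
#' change.
#'
#' @slot n_iterations outer iteration count (default 5).
#' @slot beta ART/SART relaxation parameter.
#' @slot beta_red per-iteration multiplicative reduction of beta.
#' @slot alpha TV hyperparameter scaling the descent step (default 0.002).
#' @slot alpha_red reduction factor applied to alpha when the TV step
#'   overshoots the POCS step.
#' @slot gamma_max bound controlling the evolution of alpha: alpha shrinks
#'   when the TV-step magnitude exceeds \code{gamma_max} times the POCS-step
#'   magnitude while the data residual still exceeds \code{epsilon}.
#' @slot ng number of TV-steepest-descent substeps per outer iteration
#'   (default 25; 0 degenerates to POCS-only).
#' @slot epsilon data-inconsistency tolerance (default 0).
#' @slot smoothing_delta guard in the TV-gradient norm denominators.
#' @export
setClass("ASDPOCSParams",
  representation(n_iterations = "integer", beta = "numeric", beta_red = "numeric",
                 alpha = "numeric", alpha_red = "numeric", gamma_max = "numeric",
                 ng = "integer", epsilon = "numeric", smoothing_delta = "numeric"),
  prototype(n_iterations = 5L, beta = 1.0, beta_red = 0.995, alpha = 0.002,
            alpha_red = 0.95, gamma_max = 0.95, ng = 25L, epsilon = 0,
            smoothing_delta = 1e-8),
  validity = function(object) {
    msg <- character(0)
    if (object@n_iterations < 1L) msg <- c(msg, "n_iterations must be >= 1")
    if (object@beta <= 0 || object@beta >= 2)
      msg <- c(msg, "beta must lie in (0, 2)")
    if (object@beta_red <= 0 || object@beta_red > 1)
      msg <- c(msg, "beta_red must lie in (0, 1]")
    if (object@alpha < 0) msg <- c(msg, "alpha must be nonnegative")
    if (object@alpha_red <= 0 || object@alpha_red > 1)
      msg <- c(msg, "alpha_red must lie in (0, 1]")
    if (object@ng < 0L) msg <- c(msg, "ng must be >= 0")
    if (object@epsilon < 0) msg <- c(msg, "epsilon must be >= 0")
    if (object@smoothing_delta <= 0)
      msg <- c(msg, "smoothing_delta must be positive")
    if (length(msg)) msg else TRUE
  }
)

#' SSIM parameters
#' @slot alpha,beta,gamma exponents of the luminance, contrast and structure
#'   terms (all default 1.0).
#' @slot window_size side of the square sliding window, pixels.
#' @slot taper \code{"gaussian"} (sigma \code{window_sigma}) or
#'   \code{"uniform"}.
#' @slot window_sigma standard deviation of the Gaussian taper, pixels.
#' @slot K1,K2 stabilizer constants; C1 = (K1 L)^2, C2 = (K2 L)^2,
#'   C3 = C2 / 2 with L the dynamic range.
#' @slot dynamic_range intensity range L; \code{NA} means max - min of the
#'   reference image.
#' @export
setClass("SSIMParams",
  representation(alpha = "numeric", beta = "numeric", gamma = "numeric",
                 window_size = "integer", taper = "character",
                 window_sigma = "numeric", K1 = "numeric", K2 = "numeric",
                 dynamic_range = "numeric"),
  prototype(alpha = 1.0, beta = 1.0, gamma = 1.0, window_size = 11L,
            taper = "gaussian", window_sigma = 1.5, K1 = 0.01, K2 = 0.03,
            dynamic_range = NA_real_),
  validity = function(object) {
    if (object@window_size < 2L) return("window_size must be >= 2")
    if (!object@taper %in% c("gaussian", "uniform"))
      return("taper must be 'gaussian' or 'uniform'")
    if (object@window_sigma <= 0) return("window_sigma must be positive")
    if (object@K1 < 0 || object@K2 < 0) return("K1, K2 must be nonnegative")
    TRUE
  }
)

#' Per-window SSIM map with its mean
#' @slot map matrix of per-window SSIM values in [-1, 1] (valid windows only).
#' @slot mssim arithmetic mean of the map.
#' @slot reference_id,objective_id provenance labels.
#' @export
setClass("SSIMResult",
  representation(map = "matrix", mssim = "numeric",
                 reference_id = "character", objective_id = "character"),
  validity = function(object) {
    if (abs(object@mssim - mean(object@map)) > 1e-10 * max(1, abs(object@mssim)))
      return("mssim must equal the mean of the map")
    if (any(object@map < -1 - 1e-9) || any(object@map > 1 + 1e-9))
      return("map values must lie in [-1, 1]")
    TRUE
  }
)

#' Experiment configuration
#'
#' Bundles the phantom spec, geometry, fluence, algorithm parameters, metric
#' targets and seeds for the experiment drivers.
#'
#' @slot phantom a \linkS4class{PhantomSpec}.
#' @slot geometry list of geometry configuration values (see
#'   \code{\link{geometryConfig}}).
#' @slot n_views,arc_span acquisition design of the normal (full) scan.
#' @slot fluence_per_view incident photons per pixel per view.
#' @slot fbp_kernels character vector of FBP kernels to run.
#' @slot sart,mlem,asdpocs algorithm parameter objects.
#' @slot ssim an \linkS4class{SSIMParams} used for the MSSIM comparison.
#' @slot seeds integer phantom seeds; acquisition noise seeds are derived
#'   from them.
#' @slot profile_half_length half length of FWHM profiles, mm.
#' @slot output_dir directory experiment drivers write into ("" = none).
#' @export
setClass("ExperimentConfig",
  representation(
    phantom = "PhantomSpec", geometry = "list", n_views = "integer",
    arc_span = "numeric", fluence_per_view = "numeric",
    fbp_kernels = "character", sart = "SARTParams", mlem = "MLEMParams",
    asdpocs = "ASDPOCSParams", ssim = "SSIMParams", seeds = "integer",
    profile_half_length = "numeric", output_dir = "character"
  ),
  validity = function(object) {
    msg <- character(0)
    if (length(object@seeds) < 1L) msg <- c(msg, "seeds must be nonempty")
    if (object@n_views < 3L || object@n_views %% 2L == 0L)
      msg <- c(msg, "n_views must be odd and >= 3 so the scan can be thinned")
    if (object@fluence_per_view <= 0)
      msg <- c(msg, "fluence_per_view must be positive")
    if (!all(object@fbp_kernels %in% c("ramp", "shepp_logan")))
      msg <- c(msg, "unknown FBP kernel")
    if (length(msg)) msg else TRUE
  }
)

#' Normal-versus-half projection comparison report
#' @slot records tidy data.frame of every metric measurement: one row per
#'   (seed, algorithm variant, view count, metric, target).
#' @slot summary per-variant means and standard errors across seeds, with
#'   15-to-7-view rate-of-change columns.
#' @slot seeds the phantom seeds the report covers.
#' @export
setClass("ComparisonReport",
  representation(records = "data.frame", summary = "data.frame",
                 seeds = "integer"))
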