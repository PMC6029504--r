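#' Scanner geometry configuration
#'
#' Returns the non-angular geometry constants of the simulated DBT system.
#' Defaults are representative of a commercial unit: 700 mm source-detector
#' distance, tube arc pivoting about a point on the breast-support plane
#' 660 mm below the source, stationary detector with 0.14 mm (binned) pixel
#' pitch.  All values are overridable.
#'
#' @param source_to_detector source-to-detector distance, mm.
#' @param source_to_support source-to-support distance (arc pivot radius), mm.
#' @param detector_rows,detector_cols detector pixel counts; columns run
#'   along the tube-motion axis.
#' @param pixel_pitch detector pixel pitch, mm.
#' @param detector_motion only \code{"stationary"} is supported.
#' @return named list of geometry constants.
#' @export
geometryConfig <- function(source_to_detector = 700,
                           source_to_support = 660,
                           detector_rows = 160L,
                           detector_cols = 288L,
                           pixel_pitch = 0.14,
                           detector_motion = "stationary") {
  list(source_to_detector = source_to_detector,
       source_to_support = source_to_support,
       detector_rows = as.integer(detector_rows),
       detector_cols = as.integer(detector_cols),
       pixel_pitch = pixel_pitch,
       detector_motion = detector_motion)
}

#' Build an acquisition geometry
#'
#' View angles are evenly spaced over \code{[-arc_span/2, +arc_span/2]}
#' inclusive of both endpoints (so a 15-view, 15-degree scan samples
#' -7.5, ..., +7.5 degrees with spacing 15/14 degrees).
#'
#' @param n_views number of projections (>= 1).
#' @param arc_span total angular range, degrees; 0 only if \code{n_views} is 1.
#' @param config geometry constants from \code{\link{geometryConfig}}.
#' @return an \linkS4class{AcquisitionGeometry}.
#' @examples
#' g <- makeGeometry(15, 15)
#' viewAngles(g)[1:3]
#' @export
makeGeometry <- function(n_views, arc_span, config = geometryConfig()) {
  n_views <- as.integer(n_views)
  if (n_views < 1L) stop("n_views must be >= 1")
  if (arc_span < 0) stop("arc_span must be >= 0")
  if (arc_span == 0 && n_views != 1L)
    stop("arc_span = 0 is only allowed for a single view")
  if (config$source_to_detector <= 0 || config$source_to_support <= 0 ||
      config$pixel_pitch <= 0)
    stop("non-positive distances or pitches in geometry config")
  angles <- if (n_views == 1L) 0
            else seq(-arc_span / 2, arc_span / 2, length.out = n_views)
  new("AcquisitionGeometry",
      n_views = n_views, arc_span = arc_span, view_angles = angles,
      source_to_detector = config$source_to_detector,
      source_to_support = config$source_to_support,
      detector_rows = config$detector_rows,
      detector_cols = config$detector_cols,
      pixel_pitch = config$pixel_pitch,
      detector_motion = config$detector_motion)
}

#' Construct a geometry with explicit view angles
#'
#' Used when a subset of views is retained (projection thinning): the angular
#' span is recomputed from the retained angles.
#' @param geometry template \linkS4class{AcquisitionGeometry}.
#' @param view_angles retained angles, degrees.
#' @return an \linkS4class{AcquisitionGeometry} over the given angles.
#' @keywords internal
geometryWithAngles <- function(geometry, view_angles) {
  new("AcquisitionGeometry",
      n_views = length(view_angles),
      arc_span = if (length(view_angles) > 1) max(view_angles) - min(view_angles) else 0,
      view_angles = as.numeric(view_angles),
      source_to_detector = geometry@source_to_detector,
      source_to_support = geometry@source_to_support,
      detector_rows = geometry@detector_rows,
      detector_cols = geometry@detector_cols,
      pixel_pitch = geometry@pixel_pitch,
      detector_motion = geometry@detector_motion)
}

#' @rdname accessors
#' @export
setGeneric("nViews", function(x) standardGeneric("nViews"))
#' @rdname accessors
#' @export
setGeneric("viewAngles", function(x) standardGeneric("viewAngles"))

#' Accessors for geometry and data containers
#'
#' \code{nViews} and \code{viewAngles} report the view count and angles of a
#' geometry or projection set; \code{projData}, \code{reconData},
#' \code{phantomData} extract the underlying numeric arrays;
#' \code{insertRegistry} returns the ground-truth insert table;
#' \code{residualHistory} and \code{tvHistory} the per-iteration diagnostics
#' of an iterative reconstruction.
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("nViews", "AcquisitionGeometry", function(x) x@n_views)
#' @rdname accessors
#' @export
setMethod("nViews", "ProjectionSet", function(x) x@geometry@n_views)
#' @rdname accessors
#' @export
setMethod("viewAngles", "AcquisitionGeometry", function(x) x@view_angles)
#' @rdname accessors
#' @export
setMethod("viewAngles", "ProjectionSet", function(x) x@geometry@view_angles)

#' @rdname accessors
#' @export
projData <- function(x) {
  stopifnot(is(x, "ProjectionSet"))
  x@data
}
#' @rdname accessors
#' @export
reconData <- function(x) {
  stopifnot(is(x, "ReconVolume"))
  x@data
}
#' @rdname accessors
#' @export
phantomData <- function(x) {
  stopifnot(is(x, "PhantomVolume"))
  x@data
}
#' @rdname accessors
#' @export
insertRegistry <- function(x) {
  stopifnot(is(x, "PhantomVolume"))
  x@insert_registry
}
#' @rdname accessors
#' @export
residualHistory <- function(x) {
  stopifnot(is(x, "ReconVolume"))
  x@residual_history
}
#' @rdname accessors
#' @export
tvHistory <- function(x) {
  stopifnot(is(x, "ReconVolume"))
  x@tv_history
}

setMethod("show", "AcquisitionGeometry", function(object) {
  cat(sprintf("AcquisitionGeometry: %d views over %.3f deg arc\n",
              object@n_views, object@arc_span))
  cat(sprintf("  detector %d x %d px @ %.3g mm, SDD %.0f mm, SSD %.0f mm (%s)\n",
              object@detector_cols, object@detector_rows, object@pixel_pitch,
              object@source_to_detector, object@source_to_support,
              object@detector_motion))
  invisible(object)
})

setMethod("show", "ProjectionSet", function(object) {
  d <- dim(object@data)
  noise <- if (is.na(object@noise_seed)) "noiseless"
           else sprintf("Poisson, fluence %.3g ph/px, seed %d",
                        object@per_view_fluence, object@noise_seed)
  cat(sprintf("ProjectionSet: %d views of %d x %d px (%s)\n",
              d[3], d[1], d[2], noise))
  invisible(object)
})

setMethod("show", "SystemOperator", function(object) {
  cat(sprintf("SystemOperator (%s): volume %s voxels @ %s mm, %d views\n",
              object@interpolation,
              paste(object@volume_shape, collapse = "x"),
              paste(signif(object@voxel_size, 3), collapse = "/"),
              object@geometry@n_views))
  invisible(object)
})

#' Build the forward/back projection operator
#'
#' @param geometry an \linkS4class{AcquisitionGeometry}.
#' @param volume_shape integer voxel counts (nx, ny, nz).
#' @param voxel_size voxel sizes (dx, dy, dz), mm.
#' @param interpolation \code{"joseph"} (voxel-driven bilinear, default) or
#'   \code{"siddon"} (exact voxel intersection).
#' @param volume_origin low corner of the volume, mm; default centers the
#'   volume laterally above the detector center and rests it on the
#'   breast-support plane at z = source_to_detector - source_to_support.
#' @return a \linkS4class{SystemOperator}.
#' @export
systemOperator <- function(geometry, volume_shape, voxel_size,
                           interpolation = c("joseph", "siddon"),
                           volume_origin = NULL) {
  interpolation <- match.arg(interpolation)
  volume_shape <- as.integer(volume_shape)
  if (is.null(volume_origin)) {
    support_z <- geometry@source_to_detector - geometry@source_to_support
    volume_origin <- c(-volume_shape[1] * voxel_size[1] / 2,
                       -volume_shape[2] * voxel_size[2] / 2,
                       support_z)
  }
  new("SystemOperator", geometry = geometry, volume_shape = volume_shape,
      voxel_size = as.numeric(voxel_size),
      volume_origin = as.numeric(volume_origin),
      interpolation = interpolation)
}

# Source positions (mm) for each view: the tube pivots about
# (0, 0, support_z) at radius source_to_support; at 0 deg the source sits
# directly above the detector center.
sourcePositions <- function(geometry, views = seq_len(geometry@n_views)) {
  th <- geometry@view_angles[views] * pi / 180
  r <- geometry@source_to_support
  pz <- geometry@source_to_detector - geometry@source_to_support
  cbind(r * sin(th), 0, pz + r * cos(th))
}

.detVec <- function(geometry) {
  c(-geometry@detector_cols * geometry@pixel_pitch / 2,
    -geometry@detector_rows * geometry@pixel_pitch / 2,
    geometry@pixel_pitch)
}

# Low-level forward projection of a bare array, optionally over a view
# subset.  Returns proj array [col, row, view].
.fproj <- function(x, op, views = seq_len(op@geometry@n_views)) {
  g <- op@geometry
  src <- sourcePositions(g, views)
  fun <- if (op@interpolation == "joseph") cpp_project_joseph else cpp_project_siddon
  p <- fun(as.numeric(x), op@volume_shape, op@volume_origin, op@voxel_size,
           src, .detVec(g), g@detector_cols, g@detector_rows, FALSE)
  array(p, dim = c(g@detector_cols, g@detector_rows, length(views)))
}

# Adjoint of .fproj over the same view subset; returns a volume array.
.bproj <- function(p, op, views = seq_len(op@geometry@n_views)) {
  g <- op@geometry
  src <- sourcePositions(g, views)
  fun <- if (op@interpolation == "joseph") cpp_project_joseph else cpp_project_siddon
  v <- fun(as.numeric(p), op@volume_shape, op@volume_origin, op@voxel_size,
           src, .detVec(g), g@detector_cols, g@detector_rows, TRUE)
  array(v, dim = op@volume_shape)
}

.volArray <- function(volume) {
  if (is(volume, "PhantomVolume")) volume@data
  else if (is(volume, "ReconVolume")) volume@data
  else if (is.array(volume) && length(dim(volume)) == 3L) volume
  else stop("volume must be a PhantomVolume, ReconVolume or 3D array")
}

#' Forward project a volume
#'
#' Computes, for every detector pixel of every view, the line integral of
#' attenuation (mm^-1 units times mm path length) along the ray from the
#' view's source position through the pixel center.  Linear in the volume;
#' rays that miss the volume contribute exactly 0.
#'
#' @param volume a \linkS4class{PhantomVolume}, \linkS4class{ReconVolume} or
#'   3D array matching \code{op@volume_shape}.
#' @param op a \linkS4class{SystemOperator}.
#' @return a noiseless \linkS4class{ProjectionSet}.
#' @export
forwardProject <- function(volume, op) {
  x <- .volArray(volume)
  if (!identical(dim(x), as.integer(op@volume_shape)))
    stop("volume shape does not match the operator volume_shape")
  new("ProjectionSet", data = .fproj(x, op), geometry = op@geometry,
      per_view_fluence = NA_real_, noise_seed = NA_integer_)
}

#' Back project a projection set
#'
#' Exact adjoint of \code{\link{forwardProject}} under the standard (unit
#' weight) inner products: \code{sum(forwardProject(x) * y) ==
#' sum(x * backProject(y))} up to floating-point rounding.
#'
#' @param projections a \linkS4class{ProjectionSet} consistent with
#'   \code{op@geometry}.
#' @param op a \linkS4class{SystemOperator}.
#' @return a volume-shaped numeric array.
#' @export
backProject <- function(projections, op) {
  stopifnot(is(projections, "ProjectionSet"))
  g <- op@geometry
  if (!identical(dim(projections@data),
                 c(g@detector_cols, g@detector_rows, g@n_views)))
    stop("projection dimensions do not match the operator geometry")
  if (!isTRUE(all.equal(projections@geometry@view_angles, g@view_angles)))
    stop("projection view angles do not match the operator geometry")
  .bproj(projections@data, op)
}
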