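# On-disk formats: multi-page 32-bit TIFF for image stacks plus a flat YAML
# sidecar.  The TIFF layer stores data normalized to [0, 1]; the sidecar
# records data_min/data_max so values round-trip (at 32-bit quantization,
# ~2e-10 of the data range).

.sidecarPath <- function(path) paste0(sub("\\.tiff?$", "", path), ".yaml")

.writeStack <- function(data, path, extra = list()) {
  rng <- range(data)
  scaled <- if (rng[2] > rng[1]) (data - rng[1]) / (rng[2] - rng[1]) else data * 0
  pages <- lapply(seq_len(dim(data)[3]), function(k) t(scaled[, , k]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta <- c(list(data_min = rng[1], data_max = rng[2],
                 dim = as.integer(dim(data))), extra)
  yaml::write_yaml(meta, .sidecarPath(path))
  invisible(path)
}

.readStack <- function(path) {
  meta <- yaml::read_yaml(.sidecarPath(path))
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$dim)
  data <- array(0, d)
  for (k in seq_len(d[3])) data[, , k] <- t(pages[[k]])
  if (meta$data_max > meta$data_min)
    data <- data * (meta$data_max - meta$data_min) + meta$data_min
  list(data = data, meta = meta)
}

#' Read and write acquisition geometry as a flat key-value config
#'
#' Keys are exactly the geometry field names (\code{n_views}, \code{arc_span},
#' \code{view_angles}, \code{source_to_detector}, \code{source_to_support},
#' \code{detector_rows}, \code{detector_cols}, \code{pixel_pitch},
#' \code{detector_motion}).
#'
#' @param geometry an \linkS4class{AcquisitionGeometry}.
#' @param path YAML file path.
#' @return \code{readGeometry} returns an \linkS4class{AcquisitionGeometry};
#'   \code{writeGeometry} returns the path invisibly.
#' @export
writeGeometry <- function(geometry, path) {
  yaml::write_yaml(list(
    n_views = geometry@n_views, arc_span = geometry@arc_span,
    view_angles = geometry@view_angles,
    source_to_detector = geometry@source_to_detector,
    source_to_support = geometry@source_to_support,
    detector_rows = geometry@detector_rows,
    detector_cols = geometry@detector_cols,
    pixel_pitch = geometry@pixel_pitch,
    detector_motion = geometry@detector_motion), path)
  invisible(path)
}

#' @rdname writeGeometry
#' @export
readGeometry <- function(path) {
  y <- yaml::read_yaml(path)
  new("AcquisitionGeometry",
      n_views = as.integer(y$n_views), arc_span = as.numeric(y$arc_span),
      view_angles = as.numeric(unlist(y$view_angles)),
      source_to_detector = as.numeric(y$source_to_detector),
      source_to_support = as.numeric(y$source_to_support),
      detector_rows = as.integer(y$detector_rows),
      detector_cols = as.integer(y$detector_cols),
      pixel_pitch = as.numeric(y$pixel_pitch),
      detector_motion = y$detector_motion)
}

#' Read and write projection stacks
#'
#' One TIFF page per view (32-bit, detector rows by columns) with the
#' geometry and normalization stored in a YAML sidecar next to the TIFF.
#'
#' @param projections a \linkS4class{ProjectionSet}.
#' @param path TIFF file path; the sidecar replaces the extension with
#'   \code{.yaml}.
#' @return \code{readProjections} returns a \linkS4class{ProjectionSet}.
#' @export
writeProjections <- function(projections, path) {
  stopifnot(is(projections, "ProjectionSet"))
  g <- projections@geometry
  .writeStack(projections@data, path, extra = list(
    per_view_fluence = projections@per_view_fluence,
    noise_seed = projections@noise_seed,
    n_views = g@n_views, arc_span = g@arc_span, view_angles = g@view_angles,
    source_to_detector = g@source_to_detector,
    source_to_support = g@source_to_support,
    detector_rows = g@detector_rows, detector_cols = g@detector_cols,
    pixel_pitch = g@pixel_pitch, detector_motion = g@detector_motion))
}

#' @rdname writeProjections
#' @export
readProjections <- function(path) {
  st <- .readStack(path)
  m <- st$meta
  geom <- new("AcquisitionGeometry",
              n_views = as.integer(m$n_views), arc_span = as.numeric(m$arc_span),
              view_angles = as.numeric(unlist(m$view_angles)),
              source_to_detector = as.numeric(m$source_to_detector),
              source_to_support = as.numeric(m$source_to_support),
              detector_rows = as.integer(m$detector_rows),
              detector_cols = as.integer(m$detector_cols),
              pixel_pitch = as.numeric(m$pixel_pitch),
              detector_motion = m$detector_motion)
  ns <- m$noise_seed
  fl <- m$per_view_fluence
  new("ProjectionSet", data = st$data, geometry = geom,
      per_view_fluence = if (is.null(fl) || is.na(fl)) NA_real_ else as.numeric(fl),
      noise_seed = if (is.null(ns) || is.na(ns)) NA_integer_ else as.integer(ns))
}

#' Read and write volumes as TIFF slice stacks
#'
#' One TIFF page per z slice; provenance (algorithm, parameters, voxel size,
#' iteration histories) goes to the YAML sidecar.
#'
#' @param volume a \linkS4class{ReconVolume}, \linkS4class{PhantomVolume} or
#'   3D array.
#' @param path TIFF file path.
#' @param voxel_size voxel sizes, mm (taken from the object if it has them).
#' @return \code{readVolume} returns a list with \code{data} and \code{meta}.
#' @export
writeVolume <- function(volume, path, voxel_size = NULL) {
  extra <- list()
  if (is(volume, "ReconVolume")) {
    extra <- list(algorithm = volume@algorithm,
                  params_used = volume@params_used,
                  residual_history = volume@residual_history,
                  tv_history = volume@tv_history)
  } else if (is(volume, "PhantomVolume")) {
    voxel_size <- volume@voxel_size
  }
  extra$voxel_size <- voxel_size
  .writeStack(.volArray(volume), path, extra = extra)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) .readStack(path)

#' Export the ground-truth insert registry as CSV
#'
#' Columns: id, type, x_mm, y_mm, z_mm, diameter_mm.
#'
#' @param phantom a \linkS4class{PhantomVolume}.
#' @param path CSV file path.
#' @export
writeInsertRegistry <- function(phantom, path) {
  reg <- insertRegistry(phantom)
  write.csv(reg[, c("id", "type", "x_mm", "y_mm", "z_mm", "diameter_mm")],
            path, row.names = FALSE)
  invisible(path)
}
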