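#' Simulate a DBT acquisition
#'
#' Noiseless path: the returned projections equal
#' \code{\link{forwardProject}} exactly.  Noisy path (quantum mottle): the
#' detected count in each pixel is drawn as
#' \code{N ~ Poisson(fluence * exp(-p))} under a monoenergetic Beer-Lambert
#' model, and the recorded line integral is
#' \code{-log(max(N, 1) / fluence)}; counts are floored at 1 before the log
#' so the data stay finite at very low fluence.
#'
#' @param volume a \linkS4class{PhantomVolume} (or volume array).
#' @param op a \linkS4class{SystemOperator}.
#' @param fluence_per_view incident photons per detector pixel per view;
#'   \code{NULL} or \code{NA} disables noise.
#' @param seed integer fixing the Poisson draw; \code{NULL} draws from the
#'   current RNG state.
#' @return a \linkS4class{ProjectionSet}.
#' @export
simulateAcquisition <- function(volume, op, fluence_per_view = NULL,
                                seed = NULL) {
  ps <- forwardProject(volume, op)
  if (is.null(fluence_per_view) || is.na(fluence_per_view)) return(ps)
  if (fluence_per_view <= 0) stop("fluence_per_view must be positive")
  lambda <- fluence_per_view * exp(-ps@data)
  draw <- function() array(rpois(length(lambda), lambda), dim = dim(lambda))
  counts <- if (is.null(seed)) draw() else withSeed(seed, draw())
  noisy <- -log(pmax(counts, 1) / fluence_per_view)
  new("ProjectionSet", data = noisy, geometry = ps@geometry,
      per_view_fluence = fluence_per_view,
      noise_seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Thin a normal acquisition to a half acquisition
#'
#' Keeps the views at odd 0-based indices 1, 3, ..., n-2 of an odd n-view
#' scan, i.e. (n-1)/2 views: the only equal-stride selection that stays
#' symmetric about the central angle (a 15-view scan thins to exactly 7
#' views).  The retained images are taken from the acquired data untouched;
#' nothing is re-simulated.  The geometry is rewritten with the retained
#' angles.
#'
#' @param full a \linkS4class{ProjectionSet} with an odd view count >= 3.
#' @return a \linkS4class{ProjectionSet} with (n-1)/2 views.
#' @examples
#' g <- makeGeometry(15, 15, geometryConfig(detector_rows = 4L,
#'                                          detector_cols = 4L))
#' ps <- new("ProjectionSet", data = array(0, c(4, 4, 15)), geometry = g,
#'           per_view_fluence = NA_real_, noise_seed = NA_integer_)
#' nViews(thinProjections(ps))
#' @export
thinProjections <- function(full) {
  stopifnot(is(full, "ProjectionSet"))
  n <- full@geometry@n_views
  if (n %% 2L == 0L || n < 3L)
    stop("thinning requires an odd view count >= 3")
  keep <- seq(2L, n - 1L, by = 2L)  # 1-based; odd 0-based indices
  new("ProjectionSet",
      data = full@data[, , keep, drop = FALSE],
      geometry = geometryWithAngles(full@geometry,
                                    full@geometry@view_angles[keep]),
      per_view_fluence = full@per_view_fluence,
      noise_seed = full@noise_seed)
}
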