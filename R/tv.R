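#' Total variation of a volume
#'
#' Sum over voxels of the Euclidean norm of the forward-difference gradient
#' (differences across the far boundary are absent).  Small for
#' piecewise-uniform images; noise and streak artifacts raise it.
#'
#' @param volume a 3D numeric array (or \linkS4class{ReconVolume} /
#'   \linkS4class{PhantomVolume}).
#' @return scalar TV value.
#' @export
totalVariation <- function(volume) {
  x <- .volArray(volume)
  cpp_tv(as.numeric(x), dim(x))
}

#' Gradient of the smoothed total-variation functional
#'
#' Analytic gradient of \code{sum(sqrt(|grad x|^2 + smoothing_delta^2))}; the
#' delta regularizes the norm at zero gradient.  The raw (unnormalized)
#' gradient is returned; the ASD-POCS descent normalizes it by its own
#' Euclidean norm before stepping.
#'
#' @param volume a 3D numeric array.
#' @param smoothing_delta small positive guard (default 1e-8).
#' @return volume-shaped array.
#' @export
tvGradient <- function(volume, smoothing_delta = 1e-8) {
  if (smoothing_delta <= 0) stop("smoothing_delta must be positive")
  x <- .volArray(volume)
  array(cpp_tv_grad(as.numeric(x), dim(x), smoothing_delta), dim = dim(x))
}
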