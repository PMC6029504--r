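#' Rectangular region of interest
#'
#' Builds an ROI descriptor centered on a voxel: \code{size_px} pixels in
#' (x, y) within slice \code{slice}.
#'
#' @param center 1-based (ix, iy) pixel center.
#' @param size_px (width, height) in pixels.
#' @param slice 1-based slice index.
#' @return list with 1-based index ranges \code{x}, \code{y} and \code{z}.
#' @export
roiAround <- function(center, size_px, slice) {
  hw <- (as.integer(size_px) - 1L) %/% 2L
  list(x = c(center[1] - hw[1], center[1] + (size_px[1] - 1L - hw[1])),
       y = c(center[2] - hw[2], center[2] + (size_px[2] - 1L - hw[2])),
       z = as.integer(slice))
}

#' Default CNR feature-ROI size for a mass diameter
#'
#' ROI sizes are defined by physical extent so they are pitch-independent:
#' the 3.9-mm mass gets a 2.94 x 2.94 mm window and the 4.7-mm mass a
#' 4.62 x 3.50 mm window, which at the 0.14-mm reconstruction pitch are
#' exactly 21 x 21 and 33 x 25 pixels.  Other diameters get a square ROI of
#' 0.75 x diameter.  Pixel counts are rounded down to odd.
#'
#' @param diameter_mm mass diameter, mm.
#' @param pixel_mm in-plane pixel pitch, mm.
#' @return integer (width, height) in pixels.
#' @export
featureRoiPx <- function(diameter_mm, pixel_mm) {
  odd <- function(mm) pmax(3L, as.integer(mm / pixel_mm / 2) * 2L + 1L)
  if (isTRUE(all.equal(diameter_mm, 3.9))) odd(c(2.94, 2.94))
  else if (isTRUE(all.equal(diameter_mm, 4.7))) odd(c(4.62, 3.50))
  else odd(rep(0.75 * diameter_mm, 2))
}

.roiPixels <- function(x, roi) {
  d <- dim(x)
  if (roi$x[1] < 1L || roi$y[1] < 1L || roi$x[2] > d[1] || roi$y[2] > d[2] ||
      roi$z < 1L || roi$z > d[3])
    stop("ROI extends outside the volume")
  x[roi$x[1]:roi$x[2], roi$y[1]:roi$y[2], roi$z]
}

#' Contrast-to-noise ratio
#'
#' \code{CNR = (mu_Feature - mu_BG) / sigma_BG}, with \code{mu_Feature} the
#' mean pixel value in the feature ROI, \code{mu_BG} the mean and
#' \code{sigma_BG} the sample standard deviation of the background ROI.
#' Invariant under additive intensity offsets applied to the whole image.
#' A zero background standard deviation yields a flagged undefined result.
#'
#' @param volume a \linkS4class{ReconVolume}, \linkS4class{PhantomVolume} or
#'   3D array.
#' @param feature_roi,bg_roi ROI descriptors from \code{\link{roiAround}};
#'   the background ROI needs at least 2 pixels.
#' @return list with \code{cnr}, \code{mu_feature}, \code{mu_bg},
#'   \code{sigma_bg} and \code{flag} (\code{"ok"} or \code{"undefined"}).
#' @export
cnr <- function(volume, feature_roi, bg_roi) {
  x <- .volArray(volume)
  fpix <- .roiPixels(x, feature_roi)
  bpix <- .roiPixels(x, bg_roi)
  if (length(bpix) < 2L) stop("background ROI must contain at least 2 pixels")
  mu_f <- mean(fpix)
  mu_b <- mean(bpix)
  sd_b <- sd(as.numeric(bpix))
  if (sd_b == 0)
    return(list(cnr = NA_real_, mu_feature = mu_f, mu_bg = mu_b,
                sigma_bg = sd_b, flag = "undefined"))
  list(cnr = (mu_f - mu_b) / sd_b, mu_feature = mu_f, mu_bg = mu_b,
       sigma_bg = sd_b, flag = "ok")
}

#' Rate of change between normal and half acquisitions
#'
#' \code{100 * (value_7 - value_15) / value_15}, percent.  The 15-view value
#' is the reference; a zero reference is flagged undefined.
#'
#' @param value_15 metric value at the normal (15-view) acquisition.
#' @param value_7 metric value at the half (7-view) acquisition.
#' @return percent change (\code{NA} with a warning for a zero reference).
#' @examples
#' rateOfChange(2.0, 2.5)  # +25
#' @export
rateOfChange <- function(value_15, value_7) {
  if (isTRUE(value_15 == 0)) {
    warning("rate of change undefined for a zero reference value")
    return(NA_real_)
  }
  100 * (value_7 - value_15) / value_15
}
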