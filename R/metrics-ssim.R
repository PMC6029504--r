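#' @rdname ssim
#' @param alpha,beta,gamma,window_size,taper,window_sigma,K1,K2,dynamic_range
#'   see \linkS4class{SSIMParams}.
#' @export
ssimParams <- function(alpha = 1.0, beta = 1.0, gamma = 1.0,
                       window_size = 11L, taper = c("gaussian", "uniform"),
                       window_sigma = 1.5, K1 = 0.01, K2 = 0.03,
                       dynamic_range = NA_real_) {
  taper <- match.arg(taper)
  new("SSIMParams", alpha = alpha, beta = beta, gamma = gamma,
      window_size = as.integer(window_size), taper = taper,
      window_sigma = window_sigma, K1 = K1, K2 = K2,
      dynamic_range = dynamic_range)
}

.ssimWindow <- function(params) {
  s <- params@window_size
  if (params@taper == "gaussian") {
    g <- exp(-((seq_len(s) - (s + 1) / 2)^2) / (2 * params@window_sigma^2))
    w <- outer(g, g)
  } else {
    w <- matrix(1, s, s)
  }
  w / sum(w)
}

# Weighted local first and second moments over all fully-interior windows
# (valid windows; the map is smaller than the image by window_size - 1).
.localMoments <- function(X, Y, w) {
  s <- nrow(w)
  n <- nrow(X); m <- ncol(X)
  on <- n - s + 1L; om <- m - s + 1L
  if (on < 1L || om < 1L) stop("images are smaller than the window")
  mx <- my <- xx <- yy <- xy <- matrix(0, on, om)
  for (a in seq_len(s)) for (b in seq_len(s)) {
    sx <- X[a:(a + on - 1L), b:(b + om - 1L)]
    sy <- Y[a:(a + on - 1L), b:(b + om - 1L)]
    wab <- w[a, b]
    mx <- mx + wab * sx
    my <- my + wab * sy
    xx <- xx + wab * sx * sx
    yy <- yy + wab * sy * sy
    xy <- xy + wab * sx * sy
  }
  list(mx = mx, my = my, vx = xx - mx^2, vy = yy - my^2, cxy = xy - mx * my)
}

#' Structural similarity index (SSIM) and its mean (MSSIM)
#'
#' Per sliding window, the luminance term
#' \code{l = (2 mx my + C1) / (mx^2 + my^2 + C1)}, contrast term
#' \code{c = (2 sx sy + C2) / (sx^2 + sy^2 + C2)} and structure term
#' \code{s = (cov + C3) / (sx sy + C3)} (with \code{C3 = C2 / 2}) are
#' combined as \code{l^alpha * c^beta * s^gamma}; all three exponents default
#' to 1.  The map is averaged arithmetically into the MSSIM.  Windows are
#' fully interior (valid positions only); moments are weighted by the window
#' taper.  C1 and C2 are \code{(K1 L)^2} and \code{(K2 L)^2} with L the
#' dynamic range, by default max - min of the reference image.
#'
#' @param reference,objective numeric matrices of identical shape.  In the
#'   normal-versus-half comparison the reference is the 15-view
#'   reconstruction and the objective the 7-view one.
#' @param params an \linkS4class{SSIMParams}.
#' @param reference_id,objective_id provenance labels stored in the result.
#' @return an \linkS4class{SSIMResult}.
#' @examples
#' X <- matrix(rnorm(400), 20, 20)
#' ssim(X, X)@mssim  # exactly 1
#' @export
ssim <- function(reference, objective, params = ssimParams(),
                 reference_id = "reference", objective_id = "objective") {
  validObject(params)
  if (!identical(dim(reference), dim(objective)))
    stop("reference and objective must have identical shapes")
  L <- params@dynamic_range
  if (is.na(L)) L <- max(reference) - min(reference)
  if (L <= 0) L <- 1
  C1 <- (params@K1 * L)^2
  C2 <- (params@K2 * L)^2
  C3 <- C2 / 2
  mo <- .localMoments(reference, objective, .ssimWindow(params))
  sx <- sqrt(pmax(mo$vx, 0))
  sy <- sqrt(pmax(mo$vy, 0))
  l <- (2 * mo$mx * mo$my + C1) / (mo$mx^2 + mo$my^2 + C1)
  cc <- (2 * sx * sy + C2) / (mo$vx + mo$vy + C2)
  ss <- (mo$cxy + C3) / (sx * sy + C3)
  map <- l^params@alpha * cc^params@beta * ss^params@gamma
  new("SSIMResult", map = map, mssim = mean(map),
      reference_id = reference_id, objective_id = objective_id)
}

setMethod("show", "SSIMResult", function(object) {
  cat(sprintf("SSIMResult: MSSIM = %.6f over %d windows (%s vs %s)\n",
              object@mssim, length(object@map), object@reference_id,
              object@objective_id))
  invisible(object)
})

#' Root-mean-square error between two images or volumes
#' @param a,b numeric arrays of identical shape.
#' @return \code{sqrt(mean((a - b)^2))}.
#' @export
rmse <- function(a, b) {
  if (!identical(dim(a), dim(b)) || length(a) != length(b))
    stop("a and b must have identical shapes")
  sqrt(mean((a - b)^2))
}

.qiSlice <- function(A, B, window) {
  w <- matrix(1 / window^2, window, window)
  mo <- .localMoments(A, B, w)
  num <- 4 * mo$cxy * mo$mx * mo$my
  den <- (mo$vx + mo$vy) * (mo$mx^2 + mo$my^2)
  skip <- (mo$vx + mo$vy) == 0 | (mo$mx^2 + mo$my^2) == 0
  q <- num / den
  skip <- skip | !is.finite(q)
  q[skip] <- NA_real_
  list(map = q, n_skipped = sum(skip))
}

#' Universal image quality index (QI)
#'
#' The zero-stabilizer precursor of SSIM: per sliding uniform window the
#' product of loss of correlation, luminance distortion and contrast
#' distortion, \code{4 cov mx my / ((vx + vy)(mx^2 + my^2))}, averaged over
#' all windows.  Windows with zero variance (or zero mean energy) are
#' skipped and counted.  \code{qi(x, x) = 1}.  Equals the MSSIM in the limit
#' C1 = C2 = 0 on windows with nonzero variance.
#'
#' @param a,b numeric matrices or 3D arrays of identical shape (volumes are
#'   evaluated slice by slice with in-plane windows).
#' @param window side of the square uniform sliding window (default 8).
#' @return list with \code{qi} (mean over retained windows), \code{map}
#'   (per-window values, \code{NA} where skipped; for volumes a list per
#'   slice), and \code{n_skipped}.
#' @export
qi <- function(a, b, window = 8L) {
  if (!identical(dim(a), dim(b)))
    stop("a and b must have identical shapes")
  if (length(dim(a)) == 2L) {
    r <- .qiSlice(a, b, window)
    return(list(qi = mean(r$map, na.rm = TRUE), map = r$map,
                n_skipped = r$n_skipped))
  }
  stopifnot(length(dim(a)) == 3L)
  tot <- 0; cnt <- 0L; nskip <- 0L
  maps <- vector("list", dim(a)[3])
  for (k in seq_len(dim(a)[3])) {
    r <- .qiSlice(a[, , k], b[, , k], window)
    keep <- !is.na(r$map)
    tot <- tot + sum(r$map[keep])
    cnt <- cnt + sum(keep)
    nskip <- nskip + r$n_skipped
    maps[[k]] <- r$map
  }
  list(qi = tot / cnt, map = maps, n_skipped = nskip)
}
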