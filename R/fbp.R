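#' @rdname fbp
#' @param kernel \code{"ramp"} or \code{"shepp_logan"}.
#' @export
fbpParams <- function(kernel = c("ramp", "shepp_logan")) {
  kernel <- match.arg(kernel)
  new("FBPParams", kernel = kernel, filter_axis = "motion")
}

# Frequency response (cycles/mm) of the reconstruction kernel on an
# npad-point grid with sample spacing `pitch`.  Shepp-Logan = ramp * sinc,
# rolling the response off toward Nyquist.
.fbpKernel <- function(kernel, npad, pitch) {
  f <- c(0:(npad %/% 2), -(npad %/% 2 - 1):-1) / (npad * pitch)
  H <- abs(f)
  if (kernel == "shepp_logan") {
    s <- f * pitch  # f / (2 f_nyquist)
    sinc <- ifelse(s == 0, 1, sin(pi * s) / (pi * s))
    H <- H * sinc
  }
  H
}

#' Filtered back projection
#'
#' Each view is filtered along the detector axis parallel to the tube motion
#' by a 1D frequency-domain kernel (apodized ramp; the Shepp-Logan kernel is
#' the ramp multiplied by a sinc roll-off), zero-padded to the next power of
#' two, then backprojected and normalized by the view count.  Deterministic.
#' Limited-angle geometry provides frequency support essentially along the
#' motion axis only, which is why the filtering is one-dimensional.
#'
#' @param projections a \linkS4class{ProjectionSet}.
#' @param op a \linkS4class{SystemOperator}.
#' @param params an \linkS4class{FBPParams} from \code{\link{fbpParams}}.
#' @return a \linkS4class{ReconVolume} (arbitrary linear intensity scale).
#' @export
fbp <- function(projections, op, params = fbpParams()) {
  stopifnot(is(projections, "ProjectionSet"))
  validObject(params)
  d <- projections@data
  nu <- dim(d)[1]
  nviews <- dim(d)[3]
  if (nviews < 1L) stop("projections must be nonempty")
  pitch <- projections@geometry@pixel_pitch
  npad <- 2^ceiling(log2(2 * nu))
  H <- .fbpKernel(params@kernel, npad, pitch)
  filt <- d
  for (w in seq_len(nviews)) {
    m <- rbind(d[, , w], matrix(0, npad - nu, dim(d)[2]))
    mf <- Re(mvfft(mvfft(m) * H, inverse = TRUE)) / npad
    filt[, , w] <- mf[seq_len(nu), ]
  }
  vol <- .bproj(filt, op) / nviews
  new("ReconVolume", data = vol, algorithm = "fbp",
      params_used = list(kernel = params@kernel, filter_axis = "motion",
                         n_views = nviews, pad_length = npad),
      residual_history = numeric(0), tv_history = numeric(0))
}

setMethod("show", "ReconVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ReconVolume (%s): %d x %d x %d voxels\n", object@algorithm,
              d[1], d[2], d[3]))
  if (length(object@residual_history))
    cat("  residuals:", paste(signif(object@residual_history, 4), collapse = " "),
        "\n")
  if (length(object@tv_history))
    cat("  TV:", paste(signif(object@tv_history, 4), collapse = " "), "\n")
  invisible(object)
})
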