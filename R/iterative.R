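# Per-view SART normalization weights: row sums A_v 1 (ray weight sums, one
# projection stack) and column sums A_v^T 1 (voxel weight sums, one volume
# per view).  Computed once per operator and reused by SART and ASD-POCS.
.sartNorms <- function(op) {
  g <- op@geometry
  rows <- .fproj(array(1, op@volume_shape), op)
  ones_view <- array(1, c(g@detector_cols, g@detector_rows, 1))
  cols <- lapply(seq_len(g@n_views), function(v) .bproj(ones_view, op, views = v))
  list(rows = rows, cols = cols)
}

.fnorm <- function(x) sqrt(sum(x^2))

# One SART sweep: for each view (ascending angle order)
#   x <- x + relax * A_v^T[(b_v - A_v x) / rowsum_v] / colsum_v
# with zero-weight guards, then optional per-view nonnegativity clamping.
.sartSweep <- function(x, b, op, relax, nonneg, norms, eps = 1e-8) {
  g <- op@geometry
  for (v in seq_len(g@n_views)) {
    av <- .fproj(x, op, views = v)
    r <- b[, , v] - av[, , 1]
    rw <- norms$rows[, , v]
    corr <- .bproj(array(r / pmax(rw, eps), dim = c(dim(r), 1L)), op, views = v)
    x <- x + relax * corr / pmax(norms$cols[[v]], eps)
    if (nonneg) x[x < 0] <- 0
  }
  x
}

#' @rdname sart
#' @param n_iterations,relaxation,nonnegativity see \linkS4class{SARTParams}.
#' @export
sartParams <- function(n_iterations = 5L, relaxation = 1.0,
                       nonnegativity = TRUE) {
  new("SARTParams", n_iterations = as.integer(n_iterations),
      relaxation = relaxation, nonnegativity = nonnegativity)
}

#' Simultaneous algebraic reconstruction technique
#'
#' Updates all voxels simultaneously from all rays of one projection per
#' sub-step, sweeping the views in ascending angle order; one iteration is
#' one sweep over all views.  Starts from the zero volume.  The per-iteration
#' data-residual norm ||Ax - b|| is recorded.
#'
#' @param projections a \linkS4class{ProjectionSet}.
#' @param op a \linkS4class{SystemOperator}.
#' @param params a \linkS4class{SARTParams} from \code{\link{sartParams}}.
#' @param keep_iterates if TRUE, attach the per-iteration volumes as
#'   attribute \code{"iterates"} of the result.
#' @return a \linkS4class{ReconVolume}.
#' @export
sart <- function(projections, op, params = sartParams(),
                 keep_iterates = FALSE) {
  stopifnot(is(projections, "ProjectionSet"))
  validObject(params)
  b <- projections@data
  norms <- .sartNorms(op)
  relax <- rep_len(params@relaxation, params@n_iterations)
  x <- array(0, op@volume_shape)
  res <- numeric(params@n_iterations)
  iterates <- if (keep_iterates) vector("list", params@n_iterations)
  for (it in seq_len(params@n_iterations)) {
    x <- .sartSweep(x, b, op, relax[it], params@nonnegativity, norms)
    res[it] <- .fnorm(.fproj(x, op) - b)
    if (keep_iterates) iterates[[it]] <- x
  }
  out <- new("ReconVolume", data = x, algorithm = "sart",
             params_used = list(n_iterations = params@n_iterations,
                                relaxation = relax,
                                nonnegativity = params@nonnegativity),
             residual_history = res, tv_history = numeric(0))
  if (keep_iterates) attr(out, "iterates") <- iterates
  out
}

#' @rdname mlem
#' @param n_iterations,epsilon_guard see \linkS4class{MLEMParams}.
#' @export
mlemParams <- function(n_iterations = 2L, epsilon_guard = 1e-8) {
  new("MLEMParams", n_iterations = as.integer(n_iterations),
      epsilon_guard = epsilon_guard)
}

#' Maximum-likelihood expectation maximization
#'
#' Multiplicative update \code{x <- x * A^T(b / (Ax + eps)) / A^T 1} applied
#' to the (clamped nonnegative) line-integral data treated as a nonnegative
#' sinogram.  Positivity is preserved by construction.  Initialization is a
#' uniform strictly positive volume of value \code{mean(b) / mean(A^T 1)}.
#'
#' @param projections a \linkS4class{ProjectionSet}; negative excursions are
#'   clamped to zero before use.
#' @param op a \linkS4class{SystemOperator}.
#' @param params a \linkS4class{MLEMParams} from \code{\link{mlemParams}}.
#' @param keep_iterates if TRUE, attach per-iteration volumes.
#' @return a \linkS4class{ReconVolume}.
#' @export
mlem <- function(projections, op, params = mlemParams(),
                 keep_iterates = FALSE) {
  stopifnot(is(projections, "ProjectionSet"))
  validObject(params)
  eps <- params@epsilon_guard
  b <- pmax(projections@data, 0)
  at1 <- .bproj(array(1, dim(b)), op)
  at1g <- pmax(at1, eps)
  x <- array(max(mean(b) / mean(at1g), eps), op@volume_shape)
  res <- numeric(params@n_iterations)
  iterates <- if (keep_iterates) vector("list", params@n_iterations)
  for (it in seq_len(params@n_iterations)) {
    ax <- .fproj(x, op)
    x <- x * .bproj(b / (ax + eps), op) / at1g
    res[it] <- .fnorm(.fproj(x, op) - b)
    if (keep_iterates) iterates[[it]] <- x
  }
  out <- new("ReconVolume", data = x, algorithm = "mlem",
             params_used = list(n_iterations = params@n_iterations,
                                epsilon_guard = eps),
             residual_history = res, tv_history = numeric(0))
  if (keep_iterates) attr(out, "iterates") <- iterates
  out
}

#' @rdname asdPocs
#' @param n_iterations,beta,beta_red,alpha,alpha_red,gamma_max,ng,epsilon,smoothing_delta
#'   see \linkS4class{ASDPOCSParams}.
#' @export
asdpocsParams <- function(n_iterations = 5L, beta = 1.0, beta_red = 0.995,
                          alpha = 0.002, alpha_red = 0.95, gamma_max = 0.95,
                          ng = 25L, epsilon = 0, smoothing_delta = 1e-8) {
  new("ASDPOCSParams", n_iterations = as.integer(n_iterations), beta = beta,
      beta_red = beta_red, alpha = alpha, alpha_red = alpha_red,
      gamma_max = gamma_max, ng = as.integer(ng), epsilon = epsilon,
      smoothing_delta = smoothing_delta)
}

#' Adaptive steepest descent-projection onto convex sets (ASD-POCS)
#'
#' Constrained TV-minimization reconstruction.  Each outer iteration runs
#' (1) a POCS step - one SART sweep with relaxation \code{beta} and
#' positivity enforcement - recording the image change magnitude \code{dp};
#' (2) \code{ng} TV-steepest-descent substeps, each of size
#' \code{dtvg = alpha * dp} along the unit-normalized smoothed TV gradient,
#' recording the total TV-step magnitude \code{dg}; and (3) the adaptation
#' \code{beta <- beta * beta_red}, with \code{alpha <- alpha * alpha_red}
#' whenever \code{dg > gamma_max * dp} while the data residual still exceeds
#' \code{epsilon}.  Per-iteration residual norms and TV values are recorded.
#' Deterministic given its inputs; \code{ng = 0} degenerates to the POCS-only
#' (SART with the beta schedule) trajectory, and \code{alpha -> 0} recovers
#' it continuously.
#'
#' @param projections a \linkS4class{ProjectionSet}.
#' @param op a \linkS4class{SystemOperator}.
#' @param params an \linkS4class{ASDPOCSParams} from
#'   \code{\link{asdpocsParams}} (defaults alpha = 0.002, ng = 25, 5 outer
#'   iterations).
#' @param keep_iterates if TRUE, attach per-iteration volumes.
#' @return a \linkS4class{ReconVolume} with residual and TV histories.
#' @export
asdPocs <- function(projections, op, params = asdpocsParams(),
                    keep_iterates = FALSE) {
  stopifnot(is(projections, "ProjectionSet"))
  validObject(params)
  b <- projections@data
  norms <- .sartNorms(op)
  dims <- op@volume_shape
  beta <- params@beta
  alpha <- params@alpha
  x <- array(0, dims)
  res <- numeric(params@n_iterations)
  tvh <- numeric(params@n_iterations)
  iterates <- if (keep_iterates) vector("list", params@n_iterations)
  for (it in seq_len(params@n_iterations)) {
    x0 <- x
    x <- .sartSweep(x, b, op, beta, TRUE, norms)
    dp <- .fnorm(x - x0)
    dtvg <- alpha * dp
    xt <- x
    if (params@ng > 0L && dtvg > 0) {
      xv <- as.numeric(x)
      for (i in seq_len(params@ng)) {
        g <- cpp_tv_grad(xv, dims, params@smoothing_delta)
        gn <- .fnorm(g)
        if (gn > 0) xv <- xv - dtvg * g / gn
      }
      x <- array(xv, dims)
    }
    dg <- .fnorm(x - xt)
    res[it] <- .fnorm(.fproj(x, op) - b)
    tvh[it] <- cpp_tv(as.numeric(x), dims)
    beta <- beta * params@beta_red
    if (dg > params@gamma_max * dp && res[it] > params@epsilon)
      alpha <- alpha * params@alpha_red
    if (keep_iterates) iterates[[it]] <- x
  }
  # positivity is one of the convex sets: project once more so the returned
  # volume is nonnegative even after the closing TV descent
  x[x < 0] <- 0
  out <- new("ReconVolume", data = x, algorithm = "asd_pocs",
             params_used = list(n_iterations = params@n_iterations,
                                beta = params@beta, beta_red = params@beta_red,
                                alpha = params@alpha, alpha_red = params@alpha_red,
                                gamma_max = params@gamma_max, ng = params@ng,
                                epsilon = params@epsilon,
                                smoothing_delta = params@smoothing_delta,
                                final_alpha = alpha, final_beta = beta),
             residual_history = res, tv_history = tvh)
  if (keep_iterates) attr(out, "iterates") <- iterates
  out
}
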