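# Independent brute-force oracles: plain-R reimplementations used to check
# the compiled fast paths.  Deliberately loop-based and shared with nothing
# in R/.

# Dense system matrix built ray by ray.  Row order matches the flattened
# projection array: detector column fastest, then row, then view.
denseSystemMatrix <- function(op, method = c("joseph", "siddon")) {
  method <- match.arg(method)
  g <- op@geometry
  src <- DBTrecon:::sourcePositions(g)
  nx <- op@volume_shape[1]; ny <- op@volume_shape[2]; nz <- op@volume_shape[3]
  vx0 <- op@volume_origin[1]; vy0 <- op@volume_origin[2]; vz0 <- op@volume_origin[3]
  dx <- op@voxel_size[1]; dy <- op@voxel_size[2]; dz <- op@voxel_size[3]
  nu <- g@detector_cols; nv <- g@detector_rows; pitch <- g@pixel_pitch
  px0 <- -nu * pitch / 2; py0 <- -nv * pitch / 2
  A <- matrix(0, nu * nv * g@n_views, nx * ny * nz)
  vox <- function(i0, j0, k0) 1L + i0 + nx * (j0 + ny * k0)  # 0-based in, 1-based out
  ray <- 0L
  for (w in seq_len(g@n_views)) for (v in seq_len(nv)) for (u in seq_len(nu)) {
    ray <- ray + 1L
    S <- src[w, ]
    D <- c(px0 + (u - 0.5) * pitch, py0 + (v - 0.5) * pitch, 0)
    V <- D - S
    L <- sqrt(sum(V^2))
    if (method == "joseph") {
      wgt <- dz * L / abs(V[3])
      for (k in seq_len(nz)) {
        zk <- vz0 + (k - 0.5) * dz
        t <- (zk - S[3]) / V[3]
        ui <- (S[1] + t * V[1] - vx0) / dx - 0.5
        vj <- (S[2] + t * V[2] - vy0) / dy - 0.5
        i0 <- floor(ui); j0 <- floor(vj)
        fx <- ui - i0; fy <- vj - j0
        for (di in 0:1) for (dj in 0:1) {
          ii <- i0 + di; jj <- j0 + dj
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny) next
          wt <- (if (di) fx else 1 - fx) * (if (dj) fy else 1 - fy)
          idx <- vox(ii, jj, k - 1L)
          A[ray, idx] <- A[ray, idx] + wgt * wt
        }
      }
    } else {
      lo <- c(vx0, vy0, vz0)
      hi <- lo + c(nx * dx, ny * dy, nz * dz)
      tmin <- 0; tmax <- 1; miss <- FALSE
      for (a in 1:3) {
        if (abs(V[a]) < 1e-12) {
          if (S[a] <= lo[a] || S[a] >= hi[a]) miss <- TRUE
        } else {
          tt <- sort(c((lo[a] - S[a]) / V[a], (hi[a] - S[a]) / V[a]))
          tmin <- max(tmin, tt[1]); tmax <- min(tmax, tt[2])
        }
      }
      if (miss || tmin >= tmax) next
      ts <- c(tmin, tmax)
      for (a in 1:3) {
        if (abs(V[a]) < 1e-12) next
        n_a <- c(nx, ny, nz)[a]
        d_a <- c(dx, dy, dz)[a]
        cand <- (lo[a] + (0:n_a) * d_a - S[a]) / V[a]
        ts <- c(ts, cand[cand > tmin & cand < tmax])
      }
      ts <- sort(ts)
      for (s in seq_len(length(ts) - 1L)) {
        seg <- ts[s + 1] - ts[s]
        if (seg <= 0) next
        tm <- (ts[s] + ts[s + 1]) / 2
        P <- S + tm * V
        i0 <- floor((P[1] - vx0) / dx); j0 <- floor((P[2] - vy0) / dy)
        k0 <- floor((P[3] - vz0) / dz)
        if (i0 < 0 || i0 >= nx || j0 < 0 || j0 >= ny || k0 < 0 || k0 >= nz) next
        idx <- vox(i0, j0, k0)
        A[ray, idx] <- A[ray, idx] + seg * L
      }
    }
  }
  A
}

# Split a dense matrix into per-view row blocks (same view order).
denseByView <- function(A, op) {
  g <- op@geometry
  nper <- g@detector_cols * g@detector_rows
  lapply(seq_len(g@n_views), function(w) A[(w - 1L) * nper + seq_len(nper), , drop = FALSE])
}

# Literal matrix-form SART: per view
#   x <- x + relax * t(A_v) %*% ((b_v - A_v x) / rowsum) / colsum
sartMatrixOracle <- function(Av, bv, n_iter, relax = 1, nonneg = TRUE,
                             eps = 1e-8) {
  nvox <- ncol(Av[[1]])
  relax <- rep_len(relax, n_iter)
  rows <- lapply(Av, function(A) as.numeric(A %*% rep(1, nvox)))
  cols <- lapply(Av, function(A) as.numeric(t(A) %*% rep(1, nrow(A))))
  x <- numeric(nvox)
  iterates <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    for (v in seq_along(Av)) {
      r <- bv[[v]] - as.numeric(Av[[v]] %*% x)
      x <- x + relax[it] *
        as.numeric(t(Av[[v]]) %*% (r / pmax(rows[[v]], eps))) / pmax(cols[[v]], eps)
      if (nonneg) x[x < 0] <- 0
    }
    iterates[[it]] <- x
  }
  iterates
}

# Literal matrix-form MLEM with the same initialization and guards.
mlemMatrixOracle <- function(A, b, n_iter, eps = 1e-8) {
  b <- pmax(b, 0)
  at1 <- as.numeric(t(A) %*% rep(1, nrow(A)))
  at1g <- pmax(at1, eps)
  x <- rep(max(mean(b) / mean(at1g), eps), ncol(A))
  iterates <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    ax <- as.numeric(A %*% x)
    x <- x * as.numeric(t(A) %*% (b / (ax + eps))) / at1g
    iterates[[it]] <- x
  }
  iterates
}

poissonLogLik <- function(b, ax, eps = 1e-12) sum(b * log(ax + eps) - ax)

# Naive triple-loop total variation (forward differences, one-sided edges).
naiveTV <- function(x) {
  d <- dim(x)
  tv <- 0
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    gx <- if (i < d[1]) x[i + 1, j, k] - x[i, j, k] else 0
    gy <- if (j < d[2]) x[i, j + 1, k] - x[i, j, k] else 0
    gz <- if (k < d[3]) x[i, j, k + 1] - x[i, j, k] else 0
    tv <- tv + sqrt(gx^2 + gy^2 + gz^2)
  }
  tv
}

# Naive per-window SSIM map with explicit loops over window positions.
naiveSSIMMap <- function(X, Y, window = 11L, sigma = 1.5, K1 = 0.01,
                         K2 = 0.03, L = max(X) - min(X), uniform = FALSE,
                         expo = c(1, 1, 1)) {
  w <- if (uniform) matrix(1, window, window)
       else outer(exp(-((1:window - (window + 1) / 2)^2) / (2 * sigma^2)),
                  exp(-((1:window - (window + 1) / 2)^2) / (2 * sigma^2)))
  w <- w / sum(w)
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2; C3 <- C2 / 2
  on <- nrow(X) - window + 1L; om <- ncol(X) - window + 1L
  map <- matrix(NA_real_, on, om)
  for (i in seq_len(on)) for (j in seq_len(om)) {
    sx <- X[i:(i + window - 1L), j:(j + window - 1L)]
    sy <- Y[i:(i + window - 1L), j:(j + window - 1L)]
    mx <- sum(w * sx); my <- sum(w * sy)
    vx <- sum(w * sx^2) - mx^2; vy <- sum(w * sy^2) - my^2
    cxy <- sum(w * sx * sy) - mx * my
    sdx <- sqrt(max(vx, 0)); sdy <- sqrt(max(vy, 0))
    l <- (2 * mx * my + C1) / (mx^2 + my^2 + C1)
    cc <- (2 * sdx * sdy + C2) / (vx + vy + C2)
    ss <- (cxy + C3) / (sdx * sdy + C3)
    map[i, j] <- l^expo[1] * cc^expo[2] * ss^expo[3]
  }
  map
}

# Naive universal-quality-index map (uniform window, zero stabilizers).
naiveQIMap <- function(X, Y, window = 8L) {
  on <- nrow(X) - window + 1L; om <- ncol(X) - window + 1L
  map <- matrix(NA_real_, on, om)
  for (i in seq_len(on)) for (j in seq_len(om)) {
    sx <- X[i:(i + window - 1L), j:(j + window - 1L)]
    sy <- Y[i:(i + window - 1L), j:(j + window - 1L)]
    mx <- mean(sx); my <- mean(sy)
    vx <- mean(sx^2) - mx^2; vy <- mean(sy^2) - my^2
    cxy <- mean(sx * sy) - mx * my
    if ((vx + vy) == 0 || (mx^2 + my^2) == 0) next
    q <- 4 * cxy * mx * my / ((vx + vy) * (mx^2 + my^2))
    if (is.finite(q)) map[i, j] <- q
  }
  map
}
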