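test_that("FBP maps zero projections to a zero volume and validates kernels", {
  op <- tinyOperator()
  zeros <- asProjectionSet(array(0, c(10, 10, 5)), op@geometry)
  expect_true(all(reconData(fbp(zeros, op)) == 0))
  expect_error(fbpParams("hann"))
})

test_that("FBP localizes a single bright voxel at its true in-plane position", {
  g <- makeGeometry(15, 15, geometryConfig(detector_rows = 96L,
                                           detector_cols = 112L,
                                           pixel_pitch = 0.5))
  op <- systemOperator(g, c(64L, 64L, 64L), c(0.5, 0.5, 0.5))
  x <- array(0, c(64, 64, 64))
  x[40, 25, 20] <- 1
  ps <- forwardProject(x, op)
  rec <- reconData(fbp(ps, op))
  peak <- which(rec[, , 20] == max(rec[, , 20]), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(40, 25))
})

test_that("the Shepp-Logan kernel suppresses power above half-Nyquist", {
  op <- tinyOperator(shape = c(16L, 16L, 8L), rows = 24L, cols = 32L,
                     pitch = 0.6)
  set.seed(5)
  noisy <- asProjectionSet(array(rnorm(32 * 24 * 5), c(32, 24, 5)),
                           op@geometry)
  highPower <- function(rec) {
    sl <- reconData(rec)[, , 4]
    sp <- abs(mvfft(sl))^2          # FFT along the filter (motion) axis
    n <- nrow(sp)
    idx <- seq(ceiling(n / 4) + 1, n + 1 - ceiling(n / 4))  # > half-Nyquist
    sum(sp[idx, ])
  }
  p_ramp <- highPower(fbp(noisy, op, fbpParams("ramp")))
  p_sl <- highPower(fbp(noisy, op, fbpParams("shepp_logan")))
  expect_lt(p_sl, p_ramp)
})

test_that("SART reproduces the literal matrix-form update", {
  op <- tinyOperator()
  set.seed(41)
  truth <- array(runif(512, 0, 0.1), c(8, 8, 8))
  ps <- forwardProject(truth, op)
  A <- denseSystemMatrix(op, "joseph")
  Av <- denseByView(A, op)
  bv <- lapply(1:5, function(w) as.numeric(projData(ps)[, , w]))
  oracle <- sartMatrixOracle(Av, bv, n_iter = 3, relax = 1)
  rec <- sart(ps, op, sartParams(n_iterations = 3), keep_iterates = TRUE)
  its <- attr(rec, "iterates")
  for (i in 1:3)
    expect_lt(max(abs(as.numeric(its[[i]]) - oracle[[i]])), 1e-8)
})

test_that("SART residuals strictly decrease on consistent data", {
  op <- tinyOperator(shape = c(16L, 16L, 8L), rows = 24L, cols = 24L,
                     pitch = 0.6)
  set.seed(42)
  truth <- array(runif(16 * 16 * 8, 0, 0.1), c(16, 16, 8))
  ps <- forwardProject(truth, op)
  rec <- sart(ps, op)
  expect_equal(rec@params_used$n_iterations, 5L)
  expect_true(all(diff(residualHistory(rec)) < 0))
  expect_true(all(reconData(rec) >= 0))

  zeros <- asProjectionSet(array(0, c(24, 24, 5)), op@geometry)
  expect_true(all(reconData(sart(zeros, op)) == 0))
})

test_that("MLEM reproduces the literal matrix-form update", {
  op <- tinyOperator()
  set.seed(43)
  truth <- array(runif(512, 0, 0.1), c(8, 8, 8))
  ps <- forwardProject(truth, op)
  A <- denseSystemMatrix(op, "joseph")
  oracle <- mlemMatrixOracle(A, as.numeric(projData(ps)), n_iter = 3)
  rec <- mlem(ps, op, mlemParams(n_iterations = 3), keep_iterates = TRUE)
  its <- attr(rec, "iterates")
  for (i in 1:3)
    expect_lt(max(abs(as.numeric(its[[i]]) - oracle[[i]])), 1e-8)
})

test_that("MLEM preserves positivity, kills zero data, and raises the likelihood", {
  op <- tinyOperator()
  zeros <- asProjectionSet(array(0, c(10, 10, 5)), op@geometry)
  rec0 <- mlem(zeros, op)
  expect_equal(rec0@params_used$n_iterations, 2L)
  expect_lt(max(reconData(rec0)), 1e-10)

  set.seed(44)
  truth <- array(runif(512, 0, 0.1), c(8, 8, 8))
  ps <- forwardProject(truth, op)
  rec <- mlem(ps, op, mlemParams(n_iterations = 6), keep_iterates = TRUE)
  expect_true(all(reconData(rec) >= 0))
  b <- as.numeric(projData(ps))
  ll <- vapply(attr(rec, "iterates"), function(x)
    poissonLogLik(b, as.numeric(DBTrecon:::.fproj(x, op))), 0.0)
  expect_true(all(diff(ll) > -1e-8))
})

test_that("total variation matches closed forms and the naive loop", {
  expect_equal(totalVariation(array(3.7, c(5, 6, 4))), 0)

  # single axis-aligned step of height h across one full x-plane: h * N^2
  N <- 6; h <- 0.25
  x <- array(1, c(N, N, N))
  x[4:N, , ] <- 1 + h
  expect_equal(totalVariation(x), h * N^2, tolerance = 1e-12)

  set.seed(45)
  y <- array(rnorm(216), c(6, 6, 6))
  expect_equal(totalVariation(y), naiveTV(y), tolerance = 1e-10)
})

test_that("the TV gradient matches finite differences and is shift invariant", {
  expect_true(all(tvGradient(array(1.5, c(4, 4, 4))) == 0))

  set.seed(46)
  x <- array(rnorm(125), c(5, 5, 5))
  g <- tvGradient(x)
  h <- 1e-5
  fd <- array(0, dim(x))
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h
    xm[i] <- xm[i] - h
    fd[i] <- (totalVariation(xp) - totalVariation(xm)) / (2 * h)
  }
  expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-5)

  expect_equal(tvGradient(x + 3.21), g, tolerance = 1e-12)
  expect_error(tvGradient(x, smoothing_delta = 0), "positive")
})

test_that("ASD-POCS with ng = 0 is bit-identical to POCS-only SART", {
  acq <- smallAcquisition(seed = 1L)
  p <- asdpocsParams(ng = 0L)
  rec_a <- asdPocs(acq$ps, acq$op, p)
  beta_sched <- betaSchedule(p@beta, p@beta_red, p@n_iterations)
  rec_s <- sart(acq$ps, acq$op,
                sartParams(n_iterations = p@n_iterations,
                           relaxation = beta_sched))
  expect_identical(reconData(rec_a), reconData(rec_s))
  expect_identical(residualHistory(rec_a), residualHistory(rec_s))
})

test_that("ASD-POCS recovers the SART trajectory as alpha -> 0", {
  acq <- smallAcquisition(seed = 1L)
  p <- asdpocsParams(alpha = 1e-12)
  rec_a <- asdPocs(acq$ps, acq$op, p)
  beta_sched <- betaSchedule(p@beta, p@beta_red, p@n_iterations)
  rec_s <- sart(acq$ps, acq$op,
                sartParams(n_iterations = p@n_iterations,
                           relaxation = beta_sched))
  expect_lt(max(abs(reconData(rec_a) - reconData(rec_s))), 1e-6)
})

test_that("ASD-POCS lowers TV relative to SART at matched data residuals", {
  acq <- smallAcquisition(seed = 2L)
  rec_a <- asdPocs(acq$ps, acq$op)
  expect_equal(rec_a@params_used$alpha, 0.002)
  expect_equal(rec_a@params_used$ng, 25L)
  expect_equal(rec_a@params_used$n_iterations, 5L)
  expect_true(all(reconData(rec_a) >= 0))
  rec_s <- sart(acq$ps, acq$op)
  expect_lt(tail(tvHistory(rec_a), 1), totalVariation(rec_s))
  r_a <- tail(residualHistory(rec_a), 1)
  r_s <- tail(residualHistory(rec_s), 1)
  expect_lt(abs(r_a - r_s) / r_s, 0.10)
})

test_that("reconstructions are deterministic mappings of their inputs", {
  acq <- smallAcquisition(seed = 3L)
  for (f in list(function() fbp(acq$ps, acq$op),
                 function() sart(acq$ps, acq$op),
                 function() mlem(acq$ps, acq$op),
                 function() asdPocs(acq$ps, acq$op))) {
    expect_identical(reconData(f()), reconData(f()))
  }
})
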