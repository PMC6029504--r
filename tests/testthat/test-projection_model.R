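test_that("view angles are evenly spaced, symmetric, and span the arc", {
  g <- makeGeometry(15, 15)
  expect_equal(viewAngles(g), seq(-7.5, 7.5, length.out = 15))
  expect_equal(unique(round(diff(viewAngles(g)), 12)), round(15 / 14, 12))

  g1 <- makeGeometry(1, 0)
  expect_equal(viewAngles(g1), 0)

  g7 <- makeGeometry(7, 15)
  expect_equal(max(viewAngles(g7)) - min(viewAngles(g7)), 15)
  expect_equal(viewAngles(g7), -rev(viewAngles(g7)))
})

test_that("geometry construction rejects invalid inputs", {
  expect_error(makeGeometry(0, 15), "n_views")
  expect_error(makeGeometry(3, 0), "single view")
  expect_error(makeGeometry(5, -1), "arc_span")
  expect_error(makeGeometry(5, 15, geometryConfig(pixel_pitch = -0.1)),
               "non-positive")
  expect_error(makeGeometry(5, 15, geometryConfig(source_to_detector = 0)),
               "non-positive")
})

test_that("forward projection is linear and zero at zero", {
  op <- tinyOperator()
  zero <- array(0, c(8, 8, 8))
  expect_true(all(projData(forwardProject(zero, op)) == 0))

  set.seed(11)
  x <- array(rnorm(512), c(8, 8, 8))
  y <- array(rnorm(512), c(8, 8, 8))
  pxy <- projData(forwardProject(2.5 * x - 1.25 * y, op))
  ref <- 2.5 * projData(forwardProject(x, op)) -
    1.25 * projData(forwardProject(y, op))
  expect_lt(max(abs(pxy - ref)) / max(abs(ref)), 1e-10)
})

test_that("a vertical ray through a uniform volume integrates mu * path", {
  # odd detector => a pixel sits exactly under the 0-degree source
  g <- makeGeometry(1, 0, geometryConfig(100, 80, 11L, 11L, 1.2))
  op <- systemOperator(g, c(8L, 8L, 8L), c(1, 1, 5))  # 40 mm deep
  p <- projData(forwardProject(array(0.05, c(8, 8, 8)), op))
  expect_equal(p[6, 6, 1], 2.0, tolerance = 1e-12)
})

test_that("both projectors match their dense system-matrix oracles", {
  set.seed(21)
  x <- array(runif(512), c(8, 8, 8))
  for (method in c("joseph", "siddon")) {
    op <- tinyOperator(interpolation = method)
    A <- denseSystemMatrix(op, method)
    fast <- as.numeric(projData(forwardProject(x, op)))
    dense <- as.numeric(A %*% as.numeric(x))
    expect_lt(max(abs(fast - dense)) / max(abs(dense)), 1e-5)

    y <- array(rnorm(10 * 10 * 5), c(10, 10, 5))
    bt <- as.numeric(DBTrecon:::.bproj(y, op))
    expect_lt(max(abs(bt - as.numeric(crossprod(A, as.numeric(y))))) /
                max(abs(bt)), 1e-5)
  }
})

test_that("forward and back projection are adjoint on random instances", {
  for (method in c("joseph", "siddon")) {
    op <- tinyOperator(interpolation = method)
    for (s in 1:10) {
      set.seed(s)
      x <- array(rnorm(512), c(8, 8, 8))
      y <- array(rnorm(10 * 10 * 5), c(10, 10, 5))
      lhs <- sum(DBTrecon:::.fproj(x, op) * y)
      rhs <- sum(x * DBTrecon:::.bproj(y, op))
      expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
    }
  }
})

test_that("back projection of zero is zero and a single view fills ray footprints", {
  op <- tinyOperator()
  zeros <- asProjectionSet(array(0, c(10, 10, 5)), op@geometry)
  expect_true(all(backProject(zeros, op) == 0))

  op1 <- tinyOperator(n_views = 1L, arc = 0)
  A <- denseSystemMatrix(op1, "joseph")
  ones <- array(1, c(10, 10, 1))
  bp <- as.numeric(DBTrecon:::.bproj(ones, op1))
  expect_equal(bp, as.numeric(crossprod(A, as.numeric(ones))),
               tolerance = 1e-10)
})

test_that("mirroring the volume along the tube-motion axis mirrors projections", {
  op <- tinyOperator()
  set.seed(31)
  x <- array(runif(512), c(8, 8, 8))
  p <- projData(forwardProject(x, op))
  pm <- projData(forwardProject(x[8:1, , ], op))
  expect_lt(max(abs(pm - p[10:1, , 5:1])), 1e-5)
})

test_that("shape mismatches are contract errors", {
  op <- tinyOperator()
  expect_error(forwardProject(array(0, c(4, 4, 4)), op), "shape")
  bad <- asProjectionSet(array(0, c(10, 10, 3)), tinyGeometry(n_views = 3L))
  expect_error(backProject(bad, op), "dimensions|angles")
})
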