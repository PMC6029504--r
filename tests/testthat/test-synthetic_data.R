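test_that("the default phantom registers both MC and both mass sizes", {
  spec <- phantomSpec(seed = 3L)
  expect_setequal(spec@mc_inserts$diameter_mm, c(0.29, 0.40))
  expect_setequal(spec@mass_inserts$diameter_mm, c(3.9, 4.7))
  vol <- buildPhantom(spec)
  reg <- insertRegistry(vol)
  expect_equal(nrow(reg), 4L)
  expect_setequal(reg$diameter_mm[reg$type == "mc"], c(0.29, 0.40))
  expect_setequal(reg$diameter_mm[reg$type == "mass"], c(3.9, 4.7))
  expect_true(all(phantomData(vol) >= 0))
})

test_that("pure-texture backgrounds stay within the two phase attenuations", {
  spec <- phantomSpec(mc_inserts = data.frame(), mass_inserts = data.frame(),
                      seed = 7L)
  vol <- buildPhantom(spec)
  expect_equal(nrow(insertRegistry(vol)), 0L)
  expect_gte(min(phantomData(vol)), spec@attenuation_adipose - 1e-12)
  expect_lte(max(phantomData(vol)), spec@attenuation_glandular + 1e-12)
  # mean glandular fraction close to the requested 50/50 mixture
  frac <- (mean(phantomData(vol)) - spec@attenuation_adipose) /
    (spec@attenuation_glandular - spec@attenuation_adipose)
  expect_equal(frac, 0.5, tolerance = 0.05)
})

test_that("phantom construction is deterministic in (spec, seed)", {
  a <- buildPhantom(smallPhantomSpec(seed = 5L))
  b <- buildPhantom(smallPhantomSpec(seed = 5L))
  expect_identical(phantomData(a), phantomData(b))
  c <- buildPhantom(smallPhantomSpec(seed = 6L))
  expect_false(identical(phantomData(a), phantomData(c)))
  expect_identical(insertRegistry(a), insertRegistry(c))
})

test_that("inserts outside the volume extent are rejected", {
  expect_error(
    phantomSpec(mass_inserts = data.frame(x_mm = 10, y_mm = 0, z_mm = 16,
                                          diameter_mm = 4.7,
                                          attenuation = 0.015)),
    "inside the volume extent")
})

test_that("noise off reproduces the forward projection exactly", {
  acq <- smallAcquisition()
  clean <- simulateAcquisition(acq$volume, acq$op)
  expect_identical(projData(clean),
                   projData(forwardProject(acq$volume, acq$op)))
  expect_error(simulateAcquisition(acq$volume, acq$op, -10), "positive")
})

test_that("log-Poisson noise has the delta-method moments", {
  # zero volume: p = 0, counts ~ Poisson(fluence), so the noisy line
  # integrals have mean ~0 and variance ~1/fluence
  g <- makeGeometry(1, 0, geometryConfig(100, 80, 1000L, 1000L, 0.1))
  op <- systemOperator(g, c(2L, 2L, 2L), c(1, 1, 1))
  fl <- 1e5
  ps <- simulateAcquisition(array(0, c(2, 2, 2)), op, fl, seed = 17L)
  p <- as.numeric(projData(ps))
  expect_length(p, 1e6)
  expect_lt(abs(mean(p)), 0.05 * sqrt(1 / fl))
  expect_equal(var(p), 1 / fl, tolerance = 0.05)
})

test_that("noise variance scales as 1/fluence (log-log slope -1)", {
  spec <- smallPhantomSpec(seed = 2L)
  spec@mc_inserts <- data.frame()
  spec@mass_inserts <- data.frame()
  spec@background_texture$glandular_fraction <- 0  # uniform adipose slab
  vol <- buildPhantom(spec)
  cfg <- smallExperimentConfig()
  op <- DBTrecon:::.opForConfig(cfg)
  clean <- projData(forwardProject(vol, op))
  vars <- vapply(c(1e3, 1e4, 1e5), function(fl) {
    noisy <- projData(simulateAcquisition(vol, op, fl, seed = 23L))
    var(as.numeric(noisy - clean))
  }, 0.0)
  slope <- coef(lm(log(vars) ~ log(c(1e3, 1e4, 1e5))))[2]
  expect_equal(unname(slope), -1, tolerance = 0.05)
})

test_that("expected detected counts are additive over views", {
  # with a zero volume every view expects fluence * npixels counts, so
  # halving the view count exactly halves the acquisition total
  cfgrows <- geometryConfig(100, 80, 20L, 20L, 1.0)
  op10 <- systemOperator(makeGeometry(10, 15, cfgrows), c(2L, 2L, 2L), c(1, 1, 1))
  op5 <- systemOperator(makeGeometry(5, 15, cfgrows), c(2L, 2L, 2L), c(1, 1, 1))
  fl <- 1e4
  zero <- array(0, c(2, 2, 2))
  e10 <- sum(fl * exp(-projData(forwardProject(zero, op10))))
  e5 <- sum(fl * exp(-projData(forwardProject(zero, op5))))
  expect_equal(e5, e10 / 2)
})

test_that("thinning keeps the odd-index views, bit-identical and symmetric", {
  acq <- smallAcquisition(seed = 4L)
  full <- acq$ps
  half <- thinProjections(full)
  expect_equal(nViews(half), 7L)
  expect_equal(viewAngles(half), viewAngles(full)[seq(2, 14, by = 2)])
  expect_equal(viewAngles(half), -rev(viewAngles(half)))
  # pure selection: every retained view bit-identical to its source view
  for (i in seq_len(7)) {
    expect_identical(projData(half)[, , i], projData(full)[, , 2 * i])
  }
  expect_equal(max(viewAngles(half)) - min(viewAngles(half)),
               half@geometry@arc_span)

  third <- thinProjections(half)
  expect_equal(nViews(third), 3L)
  expect_equal(viewAngles(third), viewAngles(half)[c(2, 4, 6)])
})

test_that("thinning rejects even or too-small view counts", {
  g6 <- tinyGeometry(n_views = 6L)
  expect_error(thinProjections(asProjectionSet(array(0, c(10, 10, 6)), g6)),
               "odd")
  g1 <- tinyGeometry(n_views = 1L, arc = 0)
  expect_error(thinProjections(asProjectionSet(array(0, c(10, 10, 1)), g1)),
               "odd")
})
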