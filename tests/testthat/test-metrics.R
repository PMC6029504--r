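test_that("FWHM matches closed forms on Gaussian and rectangular profiles", {
  p <- seq(-5, 5, by = 0.05)
  r <- fwhm(p, exp(-p^2 / 2))
  expect_equal(r$flag, "ok")
  expect_equal(r$fwhm, 2 * sqrt(2 * log(2)), tolerance = 0.005)

  # 3-mm rectangular pulse with edges midway between samples
  p2 <- seq(-4.75, 4.75, by = 0.5)
  v2 <- as.numeric(abs(p2) < 1.5)
  expect_equal(fwhm(p2, v2)$fwhm, 3.0, tolerance = 1e-12)
})

test_that("FWHM on a tilted background matches a dense-grid oracle", {
  f <- function(x) exp(-x^2 / (2 * 0.8^2)) + 0.5 + 0.03 * x
  coarse <- seq(-5, 5, by = 0.1)
  measured <- fwhm(coarse, f(coarse))
  dense <- seq(-5, 5, length.out = 1e4)
  oracle <- fwhm(dense, f(dense))
  expect_equal(measured$fwhm, oracle$fwhm, tolerance = 0.01)
})

test_that("FWHM is invariant under intensity scaling and offsets", {
  p <- seq(-4, 4, by = 0.08)
  v <- exp(-p^2 / 1.3)
  base <- fwhm(p, v)$fwhm
  set.seed(8)
  for (i in 1:5) {
    a <- runif(1, 0.1, 10)
    b <- runif(1, -5, 5)
    expect_equal(fwhm(p, a * v + b)$fwhm, base, tolerance = 1e-9)
  }
})

test_that("profiles without a clean interior peak are flagged, not zeroed", {
  p <- seq(-3, 3, by = 0.1)
  expect_equal(fwhm(p, rep(1, length(p)))$flag, "no_peak")
  expect_equal(fwhm(p, p)$flag, "no_peak")            # max at the boundary
  r <- fwhm(p, 2 + exp(-p^2 * 50))                    # too narrow to bracket?
  expect_true(r$flag %in% c("ok", "not_bracketed"))
  half_only <- c(rep(0, 30), seq(0, 1, length.out = 31))  # rises to the edge
  expect_false(fwhm(seq_len(61), half_only)$flag == "ok")
})

test_that("profile extraction returns three neighboring lines around an insert", {
  vol <- buildPhantom(smallPhantomSpec(seed = 9L))
  reg <- insertRegistry(vol)
  mc <- reg[reg$id == "mc_040", ]
  profs <- extractProfiles(vol, c(mc$ix, mc$iy, mc$iz), half_length = 2)
  expect_length(profs, 3L)
  for (pr in profs) expect_equal(nrow(pr), 15L)  # +/- 7 voxels at 0.28 mm

  flat <- array(1, dim(phantomData(vol)))
  fp <- extractProfiles(flat, c(mc$ix, mc$iy, mc$iz), 2,
                        voxel_size = vol@voxel_size)
  expect_true(all(vapply(fp, function(d) all(d$value == 1), TRUE)))

  expect_error(extractProfiles(vol, c(1, 22, 4), half_length = 2), "exits")
  expect_error(extractProfiles(vol, c(22, 22, 99), half_length = 2),
               "outside")
})

test_that("noiseless reconstruction peaks within one pixel of the registry", {
  # full 0.14-mm pitch so the two neighbor lines still cross the 0.4-mm MC
  spec <- phantomSpec(
    volume_extent = c(8.96, 8.96, 16), voxel_size = c(0.14, 0.14, 2),
    mc_inserts = data.frame(x_mm = 1.19, y_mm = -0.7, z_mm = 7,
                            diameter_mm = 0.4, attenuation = 0.5),
    mass_inserts = data.frame(), seed = 10L)
  vol <- buildPhantom(spec)
  g <- makeGeometry(15, 15, geometryConfig(detector_rows = 80L,
                                           detector_cols = 176L,
                                           pixel_pitch = 0.14))
  op <- systemOperator(g, dim(phantomData(vol)), spec@voxel_size)
  rec <- fbp(forwardProject(vol, op), op)
  reg <- insertRegistry(vol)
  profs <- extractProfiles(rec, c(reg$ix, reg$iy, reg$iz), 2,
                           voxel_size = spec@voxel_size)
  for (pr in profs) {
    pk <- pr$position_mm[which.max(pr$value)]
    expect_lte(abs(pk), spec@voxel_size[2] + 1e-9)
  }
})

test_that("CNR follows its defining arithmetic and flags degenerate noise", {
  x <- array(4, c(12, 12, 3))
  x[3:5, 3:5, 2] <- 10
  x[7:12, 7:12, 2] <- 4 + rep(c(-2, 2), 18)  # sd = 2 (sample sd over 36 px)
  froi <- roiAround(c(4, 4), c(3, 3), 2)
  broi <- list(x = c(7, 12), y = c(7, 12), z = 2)
  r <- cnr(x, froi, broi)
  expect_equal(r$mu_feature, 10)
  expect_equal(r$mu_bg, 4)
  expect_equal(r$cnr, 6 / r$sigma_bg)
  expect_equal(r$cnr, 3.0, tolerance = 0.02)  # sample sd ~ 2.028

  # equal means: zero regardless of noise
  y <- x; y[3:5, 3:5, 2] <- 4
  expect_equal(cnr(y, froi, broi)$cnr, 0)

  flat <- array(1, c(12, 12, 3))
  expect_equal(cnr(flat, froi, broi)$flag, "undefined")
  expect_error(cnr(x, roiAround(c(1, 1), c(5, 5), 2), broi), "outside")
})

test_that("CNR is invariant under whole-image additive offsets", {
  set.seed(12)
  x <- array(rnorm(12 * 12 * 2, mean = 5), c(12, 12, 2))
  froi <- roiAround(c(4, 4), c(3, 3), 1)
  broi <- roiAround(c(9, 9), c(5, 5), 1)
  expect_equal(cnr(x + 100, froi, broi)$cnr, cnr(x, froi, broi)$cnr,
               tolerance = 1e-9)
})

test_that("the canonical ROI sizes are the defaults at 0.14-mm pitch", {
  expect_equal(featureRoiPx(3.9, 0.14), c(21L, 21L))
  expect_equal(featureRoiPx(4.7, 0.14), c(33L, 25L))
})

test_that("SSIM is exactly one on identical images and uses unit exponents", {
  set.seed(13)
  X <- matrix(rnorm(32 * 32), 32, 32)
  r <- ssim(X, X)
  expect_true(all(r@map == 1))
  expect_equal(r@mssim, 1)
  p <- ssimParams()
  expect_equal(c(p@alpha, p@beta, p@gamma), c(1, 1, 1))
  expect_error(ssim(X, matrix(0, 16, 16)), "identical shapes")
})

test_that("the SSIM map matches a brute-force window evaluation", {
  set.seed(14)
  X <- matrix(rnorm(32 * 32), 32, 32)
  Y <- X + 0.4 * matrix(rnorm(32 * 32), 32, 32)
  r <- ssim(X, Y)
  naive <- naiveSSIMMap(X, Y)
  expect_equal(dim(r@map), dim(naive))
  expect_lt(max(abs(r@map - naive)), 1e-8)
  expect_true(all(r@map >= -1 & r@map <= 1))
})

test_that("MSSIM is symmetric at fixed dynamic range and unit exponents", {
  set.seed(15)
  X <- matrix(rnorm(24 * 24), 24, 24)
  Y <- matrix(rnorm(24 * 24), 24, 24)
  p <- ssimParams(dynamic_range = 4)
  expect_equal(ssim(X, Y, p)@mssim, ssim(Y, X, p)@mssim, tolerance = 1e-12)
})

test_that("QI matches its naive oracle and the zero-stabilizer SSIM limit", {
  set.seed(16)
  X <- matrix(rnorm(30 * 30, mean = 2), 30, 30)
  Y <- X + 0.3 * matrix(rnorm(30 * 30), 30, 30)
  r <- qi(X, Y)
  naive <- naiveQIMap(X, Y)
  expect_lt(max(abs(r$map - naive), na.rm = TRUE), 1e-8)
  expect_equal(r$qi, mean(naive, na.rm = TRUE), tolerance = 1e-10)
  expect_equal(qi(X, X)$qi, 1, tolerance = 1e-12)

  # C1 = C2 = 0 uniform-window SSIM equals QI on retained windows
  p0 <- ssimParams(window_size = 8L, taper = "uniform", K1 = 0, K2 = 0)
  s0 <- ssim(X, Y, p0)
  keep <- !is.na(r$map)
  expect_lt(max(abs(s0@map[keep] - r$map[keep])), 1e-10)
})

test_that("QI skips zero-variance windows and counts them", {
  set.seed(17)
  X <- matrix(rnorm(30 * 30), 30, 30)
  Y <- matrix(rnorm(30 * 30), 30, 30)
  X[1:16, 1:16] <- 2; Y[1:16, 1:16] <- 3  # shared constant patch
  r <- qi(X, Y)
  expect_gt(r$n_skipped, 0)
  expect_true(is.finite(r$qi))
})

test_that("RMSE and rate of change follow their defining arithmetic", {
  expect_equal(rmse(c(0, 0, 3, 4), c(0, 0, 0, 0)), 2.5)
  x <- array(rnorm(27), c(3, 3, 3))
  expect_equal(rmse(x, x), 0)
  expect_error(rmse(matrix(0, 2, 2), matrix(0, 3, 3)), "identical shapes")

  expect_equal(rateOfChange(2.0, 2.5), 25)
  expect_equal(rateOfChange(2.5, 2.0), -20)
  expect_equal(rateOfChange(3, 3), 0)
  expect_warning(v <- rateOfChange(0, 1), "zero reference")
  expect_true(is.na(v))
})
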