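# synthetic profile constructor bypassing the raster
expProfile <- function(lambda, G0w = 180, step = 2.5, len = 1000,
                       pitch = 10) {
  x <- seq(0, len, by = step)
  g <- G0w * exp(-x / lambda)
  new("DiffusionProfile", location = "L2", distUm = x, gray = g,
      graySmooth = vasq:::.smooth3(g), G0 = mean(g[1:3]),
      truncated = FALSE, pixelPitch = pitch)
}

test_that("D(n%) matches the closed form on exponential profiles", {
  for (lam in c(50, 100, 200)) {
    p <- expProfile(lam)
    d10 <- diffusionDepth(p, 10)
    # analytic: the 3-sample G0 window sits ~one step out from the wall
    expect_lt(abs(d10 - lam * log(10)), 10)
    expect_false(attr(d10, "censored"))
  }
})

test_that("D(n%) is non-increasing in n and honours its boundaries", {
  p <- expProfile(100)
  depths <- vapply(c(5, 10, 25, 50, 75, 100), function(n)
    as.numeric(diffusionDepth(p, n)), 0)
  expect_true(all(diff(depths) <= 0))
  # n = 100 on a strictly decreasing profile: essentially at the wall
  expect_lt(as.numeric(diffusionDepth(p, 100)), p@pixelPitch)
  # constant profile never crosses: censored at ray length
  flat <- new("DiffusionProfile", location = NA_character_,
              distUm = seq(0, 500, 2.5), gray = rep(120, 201),
              graySmooth = rep(120, 201), G0 = 120, truncated = FALSE,
              pixelPitch = 10)
  dd <- diffusionDepth(flat, 50)
  expect_equal(as.numeric(dd), 500)
  expect_true(attr(dd, "censored"))
  expect_error(diffusionDepth(p, 0), "nPercent")
  expect_error(diffusionDepth(p, 101), "nPercent")
})

test_that("profiles from phantom halos match the generator", {
  b <- generatePhantom(PhantomSpec(seed = 3, noiseSdGray = 0,
                                   haloScaleUm = 100))
  corr <- correctBackground(b@fluorescent)
  p <- edgePaths(b@truthGraph)[[1]]
  skm <- matrix(0L, 1024, 1024); skm[p] <- 1L
  anchor <- p[round(nrow(p) / 2), ]
  pr <- extractProfile(corr, b@truthMask, anchor, rayLengthUm = 400,
                       skeleton = skm)
  # G0 is near the wall amplitude and the decay tracks exp(-x/lambda)
  expect_gt(pr@G0, 0.85 * 180)
  mid <- which.min(abs(pr@distUm - 100))
  expect_equal(pr@gray[mid] / pr@gray[1], exp(-(pr@distUm[mid] -
                                                pr@distUm[1]) / 100),
               tolerance = 0.1)
  # trunk is ~horizontal at its midpoint, so its L-class is L1 and the
  # ray is ~vertical: mask is exited within ~trunk radius
  expect_identical(pr@location, "L1")
  d10 <- diffusionDepth(pr, 10)
  expect_lt(abs(d10 - 100 * log(10)), 10)
})

test_that("profile extraction validates anchors and flat fields", {
  m <- matrix(0L, 40, 40); m[18:22, 5:35] <- 1L
  img <- matrix(77, 40, 40)
  expect_error(extractProfile(img, VesselMask(m), c(5, 5)), "inside")
  pr <- extractProfile(img, VesselMask(m), c(20, 20), rayLengthUm = 120)
  expect_equal(pr@G0, 77, tolerance = 1e-9)
  expect_true(all(abs(pr@gray - 77) < 1e-9))
})

test_that("coverage splits signal into intra- and extravascular areas", {
  m <- matrix(0L, 50, 50); m[24:26, 10:40] <- 1L   # thin vessel
  # disk halo of radius 10 around (25, 25)
  img <- matrix(0, 50, 50)
  for (y in 1:50) for (x in 1:50)
    if ((y - 25)^2 + (x - 25)^2 <= 100) img[y, x] <- 50
  cov <- coverage(img, VesselMask(m), background = 0, pixelPitch = 10)
  expect_equal(cov$total_px, cov$intra_px + cov$extra_px)
  diskArea <- sum(img > 0)
  inMask <- sum(img > 0 & m == 1L)
  expect_equal(cov$extra_px, diskArea - inMask)
  expect_equal(cov$total_um2, cov$total_px * 100)

  # all-zero image: zero areas, ratio defined as 0
  z <- coverage(matrix(0, 50, 50), VesselMask(m), 0)
  expect_equal(z$total_px, 0)
  expect_equal(z$ratio, 0)

  # signal strictly inside the mask: extra/intra ratio 0
  inside <- matrix(0, 50, 50); inside[25, 12:38] <- 90
  ci <- coverage(inside, VesselMask(m), 0)
  expect_equal(ci$extra_px, 0)
  expect_equal(ci$ratio, 0)
})

test_that("coverage overlays label earliest and latest signal times", {
  m <- VesselMask(matrix(0L, 30, 30))
  mkDisk <- function(r) {
    img <- matrix(0, 30, 30)
    for (y in 1:30) for (x in 1:30)
      if ((y - 15)^2 + (x - 15)^2 <= r^2) img[y, x] <- 40
    img
  }
  # shrinking nested disks -> concentric rings in the earliest map
  ov <- coverageOverlay(list(mkDisk(12), mkDisk(8), mkDisk(4)), m)
  expect_identical(ov$earliest[15, 15], 1L)       # covered from the start
  expect_identical(ov$latest[15, 15], 3L)
  ring <- ov$earliest[15, 15 + 10]                # only the largest disk
  expect_identical(ring, 1L)
  expect_identical(ov$latest[15, 15 + 10], 1L)
  expect_equal(ov$table$area_ratio[1], 1)
  expect_true(all(diff(ov$table$area_ratio) < 0))
  single <- coverageOverlay(list(mkDisk(6)), m)
  expect_identical(unique(single$earliest[mkDisk(6) > 0]), 1L)
})

test_that("IVIVC regression matches exact and noisy expectations", {
  exact <- data.frame(g_ratio = c(0.1, 0.4, 0.7, 1), c_ratio = c(0.1, 0.4, 0.7, 1))
  f <- ivivcFit(exact)
  expect_equal(f@slope, 1, tolerance = 1e-12)
  expect_equal(f@r2, 1, tolerance = 1e-12)

  set.seed(5)
  g <- rep(seq(0.2, 1, 0.1), 3)
  slopes <- replicate(40, {
    ivivcFit(data.frame(g_ratio = g,
                        c_ratio = 0.75 * g + rnorm(length(g), 0, 0.01)))@slope
  })
  expect_lt(abs(mean(slopes) - 0.75), 0.03)

  # shifting all C ratios only moves the intercept
  f2 <- ivivcFit(data.frame(g_ratio = exact$g_ratio,
                            c_ratio = exact$c_ratio + 0.3))
  expect_equal(f2@slope, f@slope, tolerance = 1e-12)
  expect_equal(f2@intercept, f@intercept + 0.3, tolerance = 1e-12)

  expect_error(ivivcFit(data.frame(g_ratio = 1:2 / 2, c_ratio = 1:2 / 2)),
               "3")
  expect_error(ivivcFit(data.frame(g_ratio = rep(0.5, 4),
                                   c_ratio = runif(4))), "variance")
})
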