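test_that("noiseless calibration recovers the attenuation law exactly", {
  d <- rep(c(50, 100, 250, 500, 1000), each = 4)
  c_ <- rep(c(0.625, 2.5, 10, 20), 5)
  GB <- 220
  G <- GB * 10^-(0.249 * log10(c_ * d) + 0)
  fit <- fitCalibration(data.frame(c = c_, d = d, G = G), GB)
  expect_equal(fit@epsilon, 0.249, tolerance = 1e-10)
  expect_equal(fit@k, 0, tolerance = 1e-10)
  expect_equal(fit@r2, 1, tolerance = 1e-10)
})

test_that("doubling the path length shifts attenuation by eps*log10(2)", {
  GB <- 220
  G1 <- GB * 10^-(0.249 * log10(5 * 200))
  G2 <- GB * 10^-(0.249 * log10(5 * 400))
  expect_equal(log10(GB / G2) - log10(GB / G1), 0.249 * log10(2),
               tolerance = 1e-12)
})

test_that("noisy calibration recovers epsilon on average", {
  # scaled-down Monte Carlo (the 100-fit version runs in acceptance)
  GB <- 220
  d <- rep(c(50, 100, 250, 500, 1000, 750), each = 8)
  c_ <- rep(c(0.625, 1.25, 2.5, 5, 7.5, 10, 15, 20), 6)
  set.seed(11)
  eps_hat <- replicate(25, {
    G <- GB * 10^-(0.249 * log10(c_ * d)) + rnorm(length(d), 0, 2)
    fitCalibration(data.frame(c = c_, d = d, G = G), GB)@epsilon
  })
  expect_lt(abs(mean(eps_hat) - 0.249), 0.02)
})

test_that("degenerate calibration inputs error or warn as documented", {
  expect_error(fitCalibration(data.frame(c = c(1, 2), d = c(1, 1),
                                         G = c(10, 9)), 220), "3")
  expect_error(fitCalibration(data.frame(c = rep(2, 5), d = rep(100, 5),
                                         G = rep(50, 5)), 220),
               "rank deficient")
  expect_warning(
    fit <- fitCalibration(data.frame(c = c(1, 2, 4, 8), d = rep(100, 4),
                                     G = c(50, 40, 30, 0)), 220),
    "saturated")
})

# fixture: inlet leaf on the border (node 1) -> root (2) -> source edges
# to a bifurcation (3) and a leaf (4); targets hang off node 3
ratioFixture <- function() {
  nodes <- data.frame(id = 1:6,
                      y = c(20, 20, 10, 34, 4, 16),
                      x = c(2, 16, 28, 28, 38, 38),
                      kind = c("leaf", "root", "bifurcation", "leaf",
                               "leaf", "leaf"))
  edges <- data.frame(id = 1:5, from = c(1, 2, 2, 3, 3),
                      to = c(2, 3, 4, 5, 6),
                      length_px = c(15, 17, 19, 15, 11),
                      mean_diameter_px = c(4, 4, 4, 4, 4),
                      level = c(1L, 1L, 1L, 2L, 2L))
  makeGraph(nodes, edges, dim = c(40L, 40L))
}

test_that("concentration propagation solves the ratio form of the law", {
  g <- ratioFixture()
  img <- matrix(200, 40, 40)
  calib <- CalibrationModel(epsilon = 0.249, k = 0, GB = 220)
  cm <- propagateConcentration(g, img, calib, c0 = 5, trim = FALSE)
  expect_identical(sort(cm@sourceEdges), c(2L, 3L))  # inlet excluded
  expect_true(all(abs(cm@map$c_t - 5) < 1e-9))   # G_t = G_s, d_t = d_s

  # darken one non-source target edge to half the source grayscale
  # (junction trimming keeps the measurements of touching edges apart)
  img2 <- img
  p <- edgePaths(g)[[4]]
  img2[(p[, 2] - 1) * 40 + p[, 1]] <- 100
  cm2 <- propagateConcentration(g, img2, calib, c0 = 5, cClip = 20,
                                trim = TRUE)
  expect_equal(cm2@map$c_t[cm2@map$edge_id == 4],
               5 * 2^(1 / 0.249), tolerance = 1e-6)
  expect_equal(2^(1 / 0.249), 16.2, tolerance = 0.01)
})

test_that("darker targets imply higher concentration at fixed diameter", {
  cs <- 5; ds <- 10; eps <- 0.249
  G <- seq(40, 200, by = 20)
  ct <- cs * (ds / ds) * (200 / G)^(1 / eps)
  expect_true(all(diff(ct) < 0))
})

test_that("the forward/inverse round trip recovers truth within 1%", {
  # one noise-free phantom here; the multi-seed sweep is in acceptance
  b <- generatePhantom(PhantomSpec(seed = 8, noiseSdGray = 0))
  g <- b@truthGraph
  cm <- propagateConcentration(g, b@brightField,
                               CalibrationModel(0.249, 0), c0 = 5)
  tr <- b@truthConcentration[as.character(cm@map$edge_id)]
  expect_true(all(abs(cm@map$c_t - tr) / tr < 0.01))
  expect_true(all(cm@map$level <= 2))
})

test_that("clipping and zero-grayscale edges are flagged, not silent", {
  nodes <- data.frame(id = 1:4, y = c(20, 20, 6, 34), x = c(2, 20, 38, 38),
                      kind = c("leaf", "root", "leaf", "leaf"))
  edges <- data.frame(id = 1:3, from = c(1, 2, 2), to = c(2, 3, 4),
                      length_px = c(19, 23, 23),
                      mean_diameter_px = c(8, 4, 4), level = c(1L, 1L, 1L))
  g <- makeGraph(nodes, edges, dim = c(40L, 40L))
  img <- matrix(200, 40, 40)
  p <- edgePaths(g)[[2]]
  img[(p[, 2] - 1) * 40 + p[, 1]] <- 40     # far darker than 2*c0 allows
  cm <- propagateConcentration(g, img, CalibrationModel(0.249, 0), c0 = 5,
                               trim = FALSE)
  row <- cm@map[cm@map$edge_id == 2, ]
  expect_true(row$clipped)
  expect_equal(row$c_t, 10)                 # clipped at cClip * c0
})

test_that("concentration time courses track the selected edges", {
  nodes <- data.frame(id = 1:4, y = c(20, 20, 6, 34), x = c(2, 20, 38, 38),
                      kind = c("leaf", "root", "leaf", "leaf"))
  edges <- data.frame(id = 1:3, from = c(1, 2, 2), to = c(2, 3, 4),
                      length_px = c(19, 23, 23),
                      mean_diameter_px = c(8, 4, 4), level = c(1L, 1L, 1L))
  g <- makeGraph(nodes, edges, dim = c(40L, 40L))
  calib <- CalibrationModel(0.249, 0)
  flat <- replicate(3, propagateConcentration(
    g, matrix(200, 40, 40), calib, c0 = 5, trim = FALSE),
    simplify = FALSE)
  tc <- concentrationTimecourse(flat)
  expect_true(all(abs(diff(tc$mean_ct)) < 1e-9))
  expect_equal(tc$pct_c0, rep(100, 3), tolerance = 1e-6)

  # drug washes out of the main branches by t2: against the time-zero
  # source reference the inferred concentration collapses
  dark <- matrix(200, 40, 40)
  for (i in 2:3) {
    p <- edgePaths(g)[[i]]
    dark[(p[, 2] - 1) * 40 + p[, 1]] <- 40
  }
  m0 <- propagateConcentration(g, dark, calib, c0 = 5, trim = FALSE)
  light <- matrix(200, 40, 40)
  for (i in 2:3) {
    p <- edgePaths(g)[[i]]
    light[(p[, 2] - 1) * 40 + p[, 1]] <- 84
  }
  m2 <- propagateConcentration(g, light, calib, c0 = 5, trim = FALSE,
                               reference = m0)
  tc2 <- concentrationTimecourse(list(m0, m2), edgeIds = c(2L, 3L))
  expect_equal(tc2$mean_ct[1], 5, tolerance = 1e-9)
  expect_lt(tc2$mean_ct[2], 0.1 * tc2$mean_ct[1])

  # SEM is zero for a single-edge selection
  tc3 <- concentrationTimecourse(flat, edgeIds = 2L)
  expect_true(all(tc3$sem == 0))
  expect_error(concentrationTimecourse(flat, edgeIds = integer(0)),
               "empty")
})
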