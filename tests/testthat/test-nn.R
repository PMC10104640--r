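tinyCfg <- function(...) segModelConfig(widths = c(2, 4),
                                        discWidths = c(2, 4),
                                        seed = 3, ...)

test_that("config validation enforces the width doubling convention", {
  expect_error(segModelConfig(widths = c(8, 12)), "double")
  expect_error(segModelConfig(widths = c(-8, -16)), "positive")
  expect_error(segModelConfig(lambda = -1), "lambda")
})

test_that("the generator maps any input to a same-shape probability map", {
  model <- buildDauGan(tinyCfg())
  set.seed(1)
  x <- matrix(runif(32 * 48, 0, 255), 32, 48)
  p <- predictProb(x, model)
  expect_identical(dim(p), c(32L, 48L))
  expect_true(all(p > 0 & p < 1))
  expect_error(predictProb(matrix(0, 15, 15), model), "divisible")
})

test_that("thresholding honours its bounds", {
  model <- buildDauGan(tinyCfg())
  x <- matrix(runif(16 * 16, 0, 255), 16, 16)
  expect_true(all(segmentImage(x, model, threshold = 0)@.Data == 1L))
  expect_true(all(segmentImage(x, model, threshold = 1)@.Data == 0L))
})

test_that("attention strictly increases the parameter count", {
  withDA <- buildDauGan(tinyCfg(attention = TRUE))
  without <- buildDauGan(tinyCfg(attention = FALSE))
  expect_gt(parameterCount(withDA)["generator"],
            parameterCount(without)["generator"])
  # and the attention-free model still runs end to end
  x <- matrix(runif(256, 0, 255), 16, 16)
  expect_identical(dim(predictProb(x, without)), c(16L, 16L))
})

test_that("a dual-attention block with saturated gates is the identity", {
  # channel gate forced to ~1, spatial gate to ~0: out = x * 1 + x * 0
  p <- vasq:::.daInit(4, 2)
  p$W1 <- p$W1 * 0; p$W2 <- p$W2 * 0
  p$b2 <- rep(50, 4)          # sigmoid(50) ~ 1
  p$Ws <- p$Ws * 0; p$bs <- -50
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  out <- vasq:::.daFwd(x, p)$out
  expect_equal(out, x, tolerance = 1e-10)
})

test_that("analytic gradients agree with finite differences", {
  cfg <- tinyCfg()
  model <- buildDauGan(cfg)
  set.seed(9)
  x <- array(runif(64, 0, 255), c(8, 8, 1))
  y <- matrix(rbinom(64, 1, 0.4), 8, 8)
  loss <- function(gen) vasq:::.bce(vasq:::.gForward(gen, x, cfg)$prob, y)
  fw <- vasq:::.gForward(model$gen, x, cfg)
  g <- vasq:::.gBackward(model$gen, vasq:::.bceGrad(fw$prob, y),
                         fw$cache, cfg)
  paths <- list(list("enc", 1, "c1", "W"), list("enc", 1, "c1", "gamma"),
                list("enc", 2, "c2", "beta"), list("dec", 1, "up", "W"),
                list("da", 1, "Ws"), list("da", 1, "b2"), list("out", "W"))
  get <- function(l, p) { for (k in p) l <- l[[k]]; l }
  setv <- function(l, p, v) {
    if (length(p) == 1) { l[[p[[1]]]] <- v; return(l) }
    l[[p[[1]]]] <- setv(l[[p[[1]]]], p[-1], v)
    l
  }
  eps <- 1e-5
  for (pth in paths) {
    pv <- get(model$gen, pth)
    gv <- as.numeric(get(g, pth))
    i <- which.max(abs(gv))
    pv2 <- pv; pv2[i] <- pv[i] + eps
    up <- loss(setv(model$gen, pth, pv2))
    pv2[i] <- pv[i] - eps
    dn <- loss(setv(model$gen, pth, pv2))
    num <- (up - dn) / (2 * eps)
    expect_equal(gv[i], num, tolerance = 1e-4)
  }

  # discriminator: parameter gradient and input (label-map) gradient
  img <- matrix(runif(64, 0, 255), 8, 8)
  lab <- matrix(runif(64), 8, 8)
  df <- vasq:::.dForward(model$disc, img, lab)
  bk <- vasq:::.dBackward(model$disc, 1, df$cache)
  W <- model$disc$blocks[[1]]$W
  i <- which.max(abs(bk$g$blocks[[1]]$W))
  d2 <- model$disc; d2$blocks[[1]]$W[i] <- W[i] + eps
  d3 <- model$disc; d3$blocks[[1]]$W[i] <- W[i] - eps
  num <- (vasq:::.dForward(d2, img, lab)$logit -
          vasq:::.dForward(d3, img, lab)$logit) / (2 * eps)
  expect_equal(bk$g$blocks[[1]]$W[i], num, tolerance = 1e-4)
  j <- which.max(abs(bk$dlab))
  l2 <- lab; l2[j] <- lab[j] + eps
  l3 <- lab; l3[j] <- lab[j] - eps
  num <- (vasq:::.dForward(model$disc, img, l2)$logit -
          vasq:::.dForward(model$disc, img, l3)$logit) / (2 * eps)
  expect_equal(bk$dlab[j], num, tolerance = 1e-4)
})

test_that("training is seed-deterministic and logs both losses", {
  set.seed(2)
  img <- matrix(runif(256, 0, 255), 16, 16)
  msk <- matrix(rbinom(256, 1, 0.3), 16, 16)
  cfg <- tinyCfg(lr = 1e-3, lambda = 0.1)
  m1 <- trainDauGan(buildDauGan(cfg), list(img), list(msk), epochs = 3)
  m2 <- trainDauGan(buildDauGan(cfg), list(img), list(msk), epochs = 3)
  expect_identical(m1$log, m2$log)
  expect_true(all(c("seg_loss", "adv_loss", "disc_loss") %in%
                  names(m1$log)))
  expect_true(all(is.finite(m1$log$seg_loss)))

  # lambda = 0: pure segmentation objective, no adversarial column
  m0 <- trainDauGan(buildDauGan(tinyCfg(lr = 1e-3, lambda = 0)),
                    list(img), list(msk), epochs = 2)
  expect_false("adv_loss" %in% names(m0$log))
  expect_true(all(is.na(m0$log$disc_loss)))
  expect_error(trainDauGan(buildDauGan(cfg), list(), list()), "empty")
})
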