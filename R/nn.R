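## Dual-attention U-Net GAN for vessel segmentation, implemented directly on
## im2col/col2im kernels with hand-derived backpropagation and Adam updates.
## Feature maps are (H, W, C) arrays; convolution weights are (9*Cin) x Cout
## matrices; all randomness flows through R's RNG so training is
## reproducible for a fixed seed and thread count.

.EPS <- 1e-7

#' Segmentation model configuration
#'
#' @param widths encoder channel widths per depth; must double at each
#'   depth (conventional U-Net progression). Default 64-128-256-512.
#' @param attention use dual-attention blocks on the skip connections.
#' @param discWidths discriminator conv-block widths.
#' @param lr Adam learning rate (default 1e-4).
#' @param lambda adversarial-loss weight in the generator objective.
#' @param epochs training epochs.
#' @param seed RNG seed for initialisation and training order.
#' @param folds cross-validation fold count.
#' @param attentionReduction channel bottleneck ratio in the
#'   channel-attention branch.
#' @return a validated list of class `segModelConfig`.
#' @export
segModelConfig <- function(widths = c(64, 128, 256, 512), attention = TRUE,
                           discWidths = c(16, 32, 32), lr = 1e-4,
                           lambda = 0.1, epochs = 50, seed = 1L,
                           folds = 4L, attentionReduction = 2) {
  if (any(widths <= 0)) stop("channel widths must be positive")
  if (length(widths) > 1 && any(widths[-1] != 2 * widths[-length(widths)]))
    stop("channel widths must double at each depth")
  if (lambda < 0) stop("lambda must be >= 0")
  structure(list(widths = as.integer(widths), attention = isTRUE(attention),
                 discWidths = as.integer(discWidths), lr = lr,
                 lambda = lambda, epochs = as.integer(epochs),
                 seed = as.integer(seed), folds = as.integer(folds),
                 attentionReduction = attentionReduction),
            class = "segModelConfig")
}

## ------------------------------------------------------------- primitives

.he <- function(nr, nc, fanin) matrix(rnorm(nr * nc, 0, sqrt(2 / fanin)),
                                      nr, nc)

# no conv bias: the following BatchNorm mean-subtraction absorbs any
# per-channel offset exactly, so a bias would receive a zero gradient
.convFwd <- function(x, W) {
  d <- dim(x)
  cols <- cpp_im2col(x, d[1], d[2], d[3], 3L)
  y <- cols %*% W
  dim(y) <- c(d[1], d[2], ncol(W))
  list(out = y, cache = list(cols = cols, W = W, d = d))
}

.convBwd <- function(dy, cache) {
  d <- cache$d
  dym <- matrix(dy, d[1] * d[2], ncol(cache$W))
  list(dx = cpp_col2im(dym %*% t(cache$W), d[1], d[2], d[3], 3L),
       dW = crossprod(cache$cols, dym))
}

.bnFwd <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x); n <- d[1] * d[2]
  xm <- matrix(x, n, d[3])
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  v <- colMeans(xc * xc)
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, istd, "*")
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  dim(y) <- d
  list(out = y, cache = list(xhat = xhat, istd = istd, gamma = gamma, d = d))
}

.bnBwd <- function(dy, cache) {
  d <- cache$d; n <- d[1] * d[2]
  dym <- matrix(dy, n, d[3])
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, cache$gamma, "*")
  # dx = istd/n * (n*dxhat - sum(dxhat) - xhat*sum(dxhat*xhat))
  t1 <- sweep(dxhat, 2, colSums(dxhat) / n)
  t2 <- sweep(cache$xhat, 2, cache$gamma * dgamma / n, "*")
  dx <- sweep(t1 - t2, 2, cache$istd, "*")
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

.cbrFwd <- function(x, p) {
  cv <- .convFwd(x, p$W)
  bn <- .bnFwd(cv$out, p$gamma, p$beta)
  m <- bn$out > 0
  list(out = bn$out * m, cache = list(cv = cv$cache, bn = bn$cache, m = m))
}

.cbrBwd <- function(dy, cache) {
  dy <- dy * cache$m
  bn <- .bnBwd(dy, cache$bn)
  cv <- .convBwd(bn$dx, cache$cv)
  list(dx = cv$dx, g = list(W = cv$dW,
                            gamma = bn$dgamma, beta = bn$dbeta))
}

.poolFwd <- function(x) {
  d <- dim(x)
  r <- cpp_maxpool(x, d[1], d[2], d[3])
  list(out = r$out, cache = list(idx = r$idx, d = d))
}

.poolBwd <- function(dy, cache)
  cpp_maxpool_bwd(dy, cache$idx, cache$d[1], cache$d[2], cache$d[3])

# transposed 2x2 stride-2 convolution; W is (Cin) x (4*Cout) with column
# layout (q, cout), q = dx*2 + dy; bias omitted (the decoder Conv Block's
# BatchNorm would absorb it away from the padding border)
.tconvFwd <- function(x, W) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; Cout <- ncol(W) / 4L
  xm <- matrix(x, H * Wd, d[3])
  ym <- xm %*% W
  out <- array(0, c(2 * H, 2 * Wd, Cout))
  for (q in 0:3) {
    dy_ <- q %% 2; dx_ <- q %/% 2
    sl <- ym[, (seq_len(Cout) - 1) * 4 + q + 1, drop = FALSE]
    dim(sl) <- c(H, Wd, Cout)
    out[seq_len(H) * 2 - 1 + dy_, seq_len(Wd) * 2 - 1 + dx_, ] <- sl
  }
  list(out = out, cache = list(xm = xm, W = W, d = d, Cout = Cout))
}

.tconvBwd <- function(dy, cache) {
  d <- cache$d; H <- d[1]; Wd <- d[2]; Cout <- cache$Cout
  dym <- matrix(0, H * Wd, 4L * Cout)
  for (q in 0:3) {
    dy_ <- q %% 2; dx_ <- q %/% 2
    sl <- dy[seq_len(H) * 2 - 1 + dy_, seq_len(Wd) * 2 - 1 + dx_, ,
             drop = FALSE]
    dym[, (seq_len(Cout) - 1) * 4 + q + 1] <- matrix(sl, H * Wd, Cout)
  }
  list(dx = array(dym %*% t(cache$W), d),
       dW = crossprod(cache$xm, dym))
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# dual-attention block: channel gate (global pooling -> bottleneck ->
# sigmoid) and spatial gate (channel pooling -> 3x3 conv -> sigmoid),
# branch outputs fused by addition
.daFwd <- function(x, p) {
  d <- dim(x); n <- d[1] * d[2]; C <- d[3]
  xm <- matrix(x, n, C)
  s <- colMeans(xm)
  pre1 <- as.numeric(p$W1 %*% s + p$b1)
  z <- pmax(pre1, 0)
  pre2 <- as.numeric(p$W2 %*% z + p$b2)
  gc_ <- .sigmoid(pre2)
  m <- rowMeans(xm)
  mc <- cpp_im2col(m, d[1], d[2], 1L, 3L)
  pre_s <- as.numeric(mc %*% p$Ws + p$bs)
  gs <- .sigmoid(pre_s)
  out <- sweep(xm, 2, gc_, "*") + xm * gs
  dim(out) <- d
  list(out = out,
       cache = list(xm = xm, s = s, pre1 = pre1, z = z, gc = gc_, gs = gs,
                    mc = mc, d = d, p = p))
}

.daBwd <- function(dy, cache) {
  d <- cache$d; n <- d[1] * d[2]; C <- d[3]
  dym <- matrix(dy, n, C)
  p <- cache$p
  # channel branch
  dgc <- colSums(dym * cache$xm)
  dxm <- sweep(dym, 2, cache$gc, "*")
  dpre2 <- dgc * cache$gc * (1 - cache$gc)
  dW2 <- dpre2 %*% t(cache$z)
  db2 <- dpre2
  dz <- as.numeric(t(p$W2) %*% dpre2)
  dpre1 <- dz * (cache$pre1 > 0)
  dW1 <- dpre1 %*% t(cache$s)
  db1 <- dpre1
  ds <- as.numeric(t(p$W1) %*% dpre1)
  dxm <- dxm + matrix(ds / n, n, C, byrow = TRUE)
  # spatial branch
  dgs <- rowSums(dym * cache$xm)
  dxm <- dxm + dym * cache$gs
  dpre_s <- dgs * cache$gs * (1 - cache$gs)
  dWs <- crossprod(cache$mc, dpre_s)
  dbs <- sum(dpre_s)
  dm <- cpp_col2im(matrix(dpre_s, n, 1) %*% t(p$Ws), d[1], d[2], 1L, 3L)
  dxm <- dxm + matrix(as.numeric(dm) / C, n, C)
  dim(dxm) <- d
  list(dx = dxm, g = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                          Ws = dWs, bs = dbs))
}

## ------------------------------------------------------------ model build

.cbrInit <- function(cin, cout) list(W = .he(9 * cin, cout, 9 * cin),
                                     gamma = rep(1, cout),
                                     beta = numeric(cout))

.daInit <- function(C, r) {
  Cb <- max(1L, as.integer(round(C / r)))
  list(W1 = .he(Cb, C, C), b1 = numeric(Cb),
       W2 = .he(C, Cb, Cb), b2 = numeric(C),
       Ws = .he(9, 1, 9), bs = 0)
}

#' Build an untrained DAU-GAN model pair
#'
#' The generator is a U-Net encoder--decoder whose Conv Blocks follow a
#' convolution--BatchNorm--ReLU structure, with MaxPool downsampling,
#' transposed-convolution upsampling and, when `config$attention` is set, a
#' dual-attention block on every skip-connection path (a channel-attention
#' branch and a spatial-attention branch fused by addition). The output map
#' is produced by a 1x1 convolution and a sigmoid, so segmentation
#' probabilities lie in [0, 1] and the raster shape equals the input shape.
#' The discriminator is a stack of Conv Blocks over the (image, label map)
#' pair followed by global average pooling and a sigmoid unit.
#'
#' @param config a [segModelConfig()].
#' @return a list of class `dauGan` with elements `gen`, `disc`, `config`.
#' @export
buildDauGan <- function(config) {
  stopifnot(inherits(config, "segModelConfig"))
  set.seed(config$seed)
  w <- config$widths; D <- length(w)
  gen <- list(enc = vector("list", D), dec = vector("list", max(0, D - 1)),
              da = vector("list", max(0, D - 1)))
  cin <- 1L
  for (i in seq_len(D)) {
    gen$enc[[i]] <- list(c1 = .cbrInit(cin, w[i]), c2 = .cbrInit(w[i], w[i]))
    cin <- w[i]
  }
  for (i in rev(seq_len(D - 1))) {
    gen$dec[[i]] <- list(
      up = list(W = .he(w[i + 1], 4 * w[i], w[i + 1])),
      c1 = .cbrInit(2L * w[i], w[i]), c2 = .cbrInit(w[i], w[i]))
    if (config$attention)
      gen$da[[i]] <- .daInit(w[i], config$attentionReduction)
  }
  gen$out <- list(W = .he(w[1], 1, w[1]), b = 0)
  dw <- config$discWidths
  disc <- list(blocks = vector("list", length(dw)))
  cin <- 2L
  for (i in seq_along(dw)) {
    disc$blocks[[i]] <- .cbrInit(cin, dw[i])
    cin <- dw[i]
  }
  disc$dense <- list(W = .he(cin, 1, cin), b = 0)
  structure(list(gen = gen, disc = disc, config = config), class = "dauGan")
}

#' Number of trainable parameters
#' @param model a `dauGan` model.
#' @return named vector with generator and discriminator parameter counts.
#' @export
parameterCount <- function(model) {
  cnt <- function(x) if (is.list(x)) sum(vapply(x, cnt, 0)) else length(x)
  c(generator = cnt(model$gen), discriminator = cnt(model$disc))
}

## --------------------------------------------------------------- forward

.gForward <- function(gen, x, config) {
  w <- config$widths; D <- length(w)
  d <- dim(x)
  f <- 2^(D - 1)
  if (d[1] %% f != 0 || d[2] %% f != 0)
    stop(sprintf(paste0("input %dx%d not divisible by 2^%d; pad to %dx%d"),
                 d[1], d[2], D - 1,
                 ceiling(d[1] / f) * f, ceiling(d[2] / f) * f))
  cache <- list(enc = vector("list", D), pool = vector("list", D - 1),
                dec = vector("list", max(0, D - 1)),
                da = vector("list", max(0, D - 1)))
  h <- x
  skips <- vector("list", D - 1)
  for (i in seq_len(D)) {
    a <- .cbrFwd(h, gen$enc[[i]]$c1)
    b <- .cbrFwd(a$out, gen$enc[[i]]$c2)
    cache$enc[[i]] <- list(c1 = a$cache, c2 = b$cache)
    h <- b$out
    if (i < D) {
      skips[[i]] <- h
      p <- .poolFwd(h)
      cache$pool[[i]] <- p$cache
      h <- p$out
    }
  }
  for (i in rev(seq_len(D - 1))) {
    up <- .tconvFwd(h, gen$dec[[i]]$up$W)
    s <- skips[[i]]
    if (config$attention) {
      da <- .daFwd(s, gen$da[[i]])
      cache$da[[i]] <- da$cache
      s <- da$out
    }
    hcat <- array(c(up$out, s), dim = dim(up$out) + c(0, 0, dim(s)[3]))
    a <- .cbrFwd(hcat, gen$dec[[i]]$c1)
    b <- .cbrFwd(a$out, gen$dec[[i]]$c2)
    cache$dec[[i]] <- list(up = up$cache, c1 = a$cache, c2 = b$cache,
                           ccat = dim(up$out)[3])
    h <- b$out
  }
  hm <- matrix(h, d[1] * d[2], w[1])
  logit <- as.numeric(hm %*% gen$out$W) + gen$out$b
  prob <- .sigmoid(logit)
  cache$outHm <- hm
  cache$prob <- prob
  cache$dimHW <- d[1:2]
  list(prob = matrix(prob, d[1], d[2]), cache = cache)
}

# dprob: gradient of the loss w.r.t. the probability map (H x W).
# Returns gradients in the same nested structure as the generator params.
.gBackward <- function(gen, dprob, cache, config) {
  w <- config$widths; D <- length(w)
  g <- list(enc = vector("list", D), dec = vector("list", max(0, D - 1)),
            da = vector("list", max(0, D - 1)))
  p <- cache$prob
  dlogit <- as.numeric(dprob) * p * (1 - p)
  g$out <- list(W = crossprod(cache$outHm, dlogit), b = sum(dlogit))
  dh <- matrix(dlogit, ncol = 1) %*% t(gen$out$W)
  dh <- array(dh, c(cache$dimHW, w[1]))
  dskip <- vector("list", max(0, D - 1))
  # the forward decoder ran i = D-1, ..., 1, so backprop ascends i = 1..D-1
  for (i in seq_len(D - 1)) {
    b <- .cbrBwd(dh, cache$dec[[i]]$c2)
    a <- .cbrBwd(b$dx, cache$dec[[i]]$c1)
    ccat <- cache$dec[[i]]$ccat
    dup <- a$dx[, , seq_len(ccat), drop = FALSE]
    ds <- a$dx[, , -seq_len(ccat), drop = FALSE]
    if (config$attention) {
      da <- .daBwd(ds, cache$da[[i]])
      g$da[[i]] <- da$g
      ds <- da$dx
    }
    dskip[[i]] <- ds
    up <- .tconvBwd(dup, cache$dec[[i]]$up)
    g$dec[[i]] <- list(up = list(W = up$dW), c1 = a$g, c2 = b$g)
    dh <- up$dx
  }
  # dh is now the gradient at the bottleneck (encoder D output); walk the
  # encoder back down, merging each skip gradient after the pool backward
  for (i in rev(seq_len(D))) {
    if (i < D) {
      dh <- .poolBwd(dh, cache$pool[[i]])
      dh <- dh + dskip[[i]]
    }
    b <- .cbrBwd(dh, cache$enc[[i]]$c2)
    a <- .cbrBwd(b$dx, cache$enc[[i]]$c1)
    g$enc[[i]] <- list(c1 = a$g, c2 = b$g)
    dh <- a$dx
  }
  g
}

## ---------------------------------------------------------- discriminator

.dForward <- function(disc, img, lab) {
  d <- dim(img)
  x <- array(c(img / 255, lab), c(d[1], d[2], 2L))
  nb <- length(disc$blocks)
  cache <- list(blocks = vector("list", nb), pool = vector("list", nb - 1))
  for (i in seq_len(nb)) {
    r <- .cbrFwd(x, disc$blocks[[i]])
    cache$blocks[[i]] <- r$cache
    x <- r$out
    if (i < nb) {
      pl <- .poolFwd(x)
      cache$pool[[i]] <- pl$cache
      x <- pl$out
    }
  }
  dd <- dim(x)
  xm <- matrix(x, dd[1] * dd[2], dd[3])
  gap <- colMeans(xm)
  logit <- sum(gap * disc$dense$W) + disc$dense$b
  cache$gap <- gap
  cache$dd <- dd
  cache$nHW <- dd[1] * dd[2]
  list(p = .sigmoid(logit), logit = logit, cache = cache)
}

# dlogit: scalar gradient at the discriminator logit. Returns param grads
# (same structure as disc) and the gradient w.r.t. the label-map channel.
.dBackward <- function(disc, dlogit, cache) {
  g <- list(blocks = vector("list", length(disc$blocks)))
  g$dense <- list(W = matrix(dlogit * cache$gap, ncol = 1), b = dlogit)
  dgap <- dlogit * as.numeric(disc$dense$W)
  dx <- array(rep(dgap / cache$nHW, each = cache$nHW), cache$dd)
  nb <- length(disc$blocks)
  for (i in rev(seq_len(nb))) {
    if (i < nb) dx <- .poolBwd(dx, cache$pool[[i]])
    r <- .cbrBwd(dx, cache$blocks[[i]])
    g$blocks[[i]] <- r$g
    dx <- r$dx
  }
  list(g = g, dlab = dx[, , 2])
}

## ------------------------------------------------------------------ Adam

.adamInit <- function(par) {
  if (is.list(par)) return(lapply(par, .adamInit))
  list(m = par * 0, v = par * 0)
}

.adamStep <- function(par, grad, st, lr, t, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  if (is.list(par) && !identical(names(par), c("m", "v"))) {
    for (nm in seq_along(par)) {
      if (is.null(par[[nm]]) || is.null(grad[[nm]])) next
      r <- .adamStep(par[[nm]], grad[[nm]], st[[nm]], lr, t, b1, b2, eps)
      par[[nm]] <- r$par
      st[[nm]] <- r$st
    }
    return(list(par = par, st = st))
  }
  g <- as.numeric(grad)
  st$m <- b1 * st$m + (1 - b1) * g
  st$v <- b2 * st$v + (1 - b2) * g * g
  mh <- st$m / (1 - b1^t)
  vh <- st$v / (1 - b2^t)
  list(par = par - lr * mh / (sqrt(vh) + eps), st = st)
}

## -------------------------------------------------------------- training

#' Train a DAU-GAN on labelled image/mask pairs
#'
#' Alternating adversarial training: each step updates the discriminator on
#' a real (image, ground-truth) and a fake (image, generated) pair, then
#' updates the generator on per-pixel binary cross-entropy plus
#' `lambda` times the adversarial loss. With `lambda = 0` the objective
#' reduces to pure segmentation loss and the log carries no adversarial
#' column. Training is deterministic for a fixed config seed and thread
#' count; a non-finite loss aborts with a diagnostic.
#'
#' @param model a `dauGan` from [buildDauGan()].
#' @param images list of [GrayImage-class] (or matrices) on the 0-255 scale.
#' @param masks list of [VesselMask-class] (or 0/1 matrices).
#' @param epochs training epochs (defaults to the config value).
#' @return the model with trained weights and a `log` element: a data.frame
#'   of per-epoch mean generator segmentation loss, adversarial loss (when
#'   `lambda > 0`) and discriminator loss.
#' @export
trainDauGan <- function(model, images, masks, epochs = NULL) {
  stopifnot(inherits(model, "dauGan"))
  if (!length(images)) stop("training set is empty")
  if (length(images) != length(masks))
    stop("images and masks must pair up")
  cfg <- model$config
  if (is.null(epochs)) epochs <- cfg$epochs
  imgs <- lapply(images, function(x) {
    m <- if (is(x, "GrayImage")) x@.Data else as.matrix(x)
    array(m, c(dim(m), 1L))
  })
  labs <- lapply(masks, function(x) {
    m <- if (is(x, "VesselMask")) x@.Data else as.matrix(x)
    matrix(as.numeric(m), nrow(m), ncol(m))
  })
  gen <- model$gen; disc <- model$disc
  stG <- .adamInit(gen); stD <- .adamInit(disc)
  tG <- 0L; tD <- 0L
  adv <- cfg$lambda > 0
  log <- data.frame(epoch = integer(0), seg_loss = numeric(0),
                    disc_loss = numeric(0))
  if (adv) log$adv_loss <- numeric(0)
  set.seed(cfg$seed + 1L)
  for (ep in seq_len(epochs)) {
    ord <- sample(length(imgs))
    segL <- advL <- dscL <- 0
    for (s in ord) {
      x <- imgs[[s]]; y <- labs[[s]]
      fw <- .gForward(gen, x, cfg)
      fake <- fw$prob
      if (adv) {
        # discriminator step on the real and the (detached) fake pair
        dr <- .dForward(disc, x[, , 1], y)
        df <- .dForward(disc, x[, , 1], fake)
        lD <- (.bce(dr$p, 1) + .bce(df$p, 0)) / 2
        dlr <- (dr$p - 1) / 2      # d/dlogit of BCE(sigmoid(logit), y)
        dlf <- (df$p - 0) / 2
        gr <- .dBackward(disc, dlr, dr$cache)$g
        gf <- .dBackward(disc, dlf, df$cache)$g
        tD <- tD + 1L
        r <- .adamStep(disc, .sumGrads(gr, gf), stD, cfg$lr, tD)
        disc <- r$par; stD <- r$st
        dscL <- dscL + lD
      }
      # generator step
      lSeg <- .bce(fake, y)
      dprob <- .bceGrad(fake, y)
      if (adv) {
        dfa <- .dForward(disc, x[, , 1], fake)
        lAdv <- .bce(dfa$p, 1)
        bk <- .dBackward(disc, dfa$p - 1, dfa$cache)
        dprob <- dprob + cfg$lambda * bk$dlab
        advL <- advL + lAdv
      }
      if (!is.finite(lSeg))
        stop("non-finite generator loss at epoch ", ep,
             ", sample ", s, "; reduce the learning rate")
      gG <- .gBackward(gen, dprob, fw$cache, cfg)
      tG <- tG + 1L
      r <- .adamStep(gen, gG, stG, cfg$lr, tG)
      gen <- r$par; stG <- r$st
      segL <- segL + lSeg
    }
    n <- length(imgs)
    row <- data.frame(epoch = ep, seg_loss = segL / n,
                      disc_loss = if (adv) dscL / n else NA_real_)
    if (adv) row$adv_loss <- advL / n
    log <- rbind(log, row)
  }
  model$gen <- gen
  model$disc <- disc
  model$log <- log
  model
}

.sumGrads <- function(a, b) {
  if (is.list(a)) {
    for (i in seq_along(a)) a[[i]] <- .sumGrads(a[[i]], b[[i]])
    return(a)
  }
  a + b
}

#' Segment an image with a trained generator
#'
#' @param image a [GrayImage-class] or matrix on the 0-255 scale.
#' @param model a trained `dauGan`.
#' @param threshold probability cut-off (default 0.5); pixels with
#'   probability >= threshold become foreground.
#' @return a [VesselMask-class].
#' @export
segmentImage <- function(image, model, threshold = 0.5) {
  m <- if (is(image, "GrayImage")) image@.Data else as.matrix(image)
  fw <- .gForward(model$gen, array(m, c(dim(m), 1L)), model$config)
  VesselMask((fw$prob >= threshold) * 1L)
}

#' Generator probability map (no thresholding)
#' @inheritParams segmentImage
#' @return numeric matrix of per-pixel vessel probabilities in [0, 1].
#' @export
predictProb <- function(image, model) {
  m <- if (is(image, "GrayImage")) image@.Data else as.matrix(image)
  .gForward(model$gen, array(m, c(dim(m), 1L)), model$config)$prob
}

## ---------------------------------------------------------------- losses

.bce <- function(p, y) {
  p <- pmin(1 - .EPS, pmax(.EPS, p))
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

.bceGrad <- function(p, y) {
  p <- pmin(1 - .EPS, pmax(.EPS, p))
  (-(y / p) + (1 - y) / (1 - p)) / length(p)
}
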