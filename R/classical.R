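## Classical (non-learned) segmentation fallback, manual-correction
## overlays, and cross-validated evaluation.

#' Classical vessel segmentation
#'
#' Background-referenced adaptive thresholding followed by morphological
#' opening and largest-component retention. Vessels are assumed darker than
#' the background (`darkVessels = TRUE`, the bright-field convention); set
#' the flag to `FALSE` for bright-on-dark (fluorescent-like) images.
#'
#' @param image [GrayImage-class] or matrix (0-255).
#' @param darkVessels invert contrast before thresholding (default TRUE).
#' @param window adaptive-threshold half-width in pixels.
#' @param offset threshold offset on the 0-255 grayscale: a pixel is
#'   foreground when it exceeds its local mean by more than this.
#' @param openRadius radius of the morphological opening brush (0 = skip).
#' @param keepLargest retain only the largest connected component.
#' @return a [VesselMask-class].
#' @export
classicalSegment <- function(image, darkVessels = TRUE, window = 64,
                             offset = 25, openRadius = 1,
                             keepLargest = TRUE) {
  img <- if (is(image, "GrayImage")) image@.Data else as.matrix(image)
  x <- if (darkVessels) (255 - img) / 255 else img / 255
  window <- min(window, floor((min(dim(img)) - 1) / 2))
  th <- thresh(Image(x), w = window, h = window, offset = offset / 255)
  m <- imageData(th)
  if (openRadius > 0) {
    brush <- makeBrush(2 * openRadius + 1, shape = "disc")
    m <- imageData(opening(Image(m), brush))
  }
  # vessels are solid in projection: noise pinholes would otherwise turn
  # into skeleton rings and break the tree topology downstream
  m <- imageData(fillHull(Image(m)))
  if (keepLargest && any(m > 0)) {
    lab <- imageData(bwlabel(Image(m)))
    tab <- tabulate(lab[lab > 0])
    if (length(tab)) m <- (lab == which.max(tab)) * 1
  }
  VesselMask(m)
}

#' Apply a manual-correction layer to a mask
#'
#' Deterministic overlay of expert corrections: pixels in `add` become
#' foreground, pixels in `remove` become background, everything else keeps
#' its predicted value. When a pixel is in both layers, remove wins (the
#' documented precedence).
#'
#' @param mask a [VesselMask-class].
#' @param add,remove 0/1 matrices (or masks) of the same shape; either may
#'   be NULL.
#' @param provenance if TRUE, return a list with the corrected mask and the
#'   logical matrix of changed pixels.
#' @return the corrected [VesselMask-class] (or a list, see `provenance`).
#' @export
applyCorrections <- function(mask, add = NULL, remove = NULL,
                             provenance = FALSE) {
  m0 <- .maskMat(mask)
  m <- m0
  if (!is.null(add)) {
    a <- .maskMat(add)
    if (!identical(dim(a), dim(m))) stop("correction layer shape mismatch")
    m[a == 1L] <- 1L
  }
  if (!is.null(remove)) {
    r <- .maskMat(remove)
    if (!identical(dim(r), dim(m))) stop("correction layer shape mismatch")
    m[r == 1L] <- 0L
  }
  out <- VesselMask(m)
  if (provenance) list(mask = out, changed = m != m0) else out
}

#' Cross-validated segmentation evaluation
#'
#' Deterministic seeded shuffle into `k` folds; for each fold a model is
#' fitted on the remaining samples via `trainer` and evaluated on the
#' held-out pairs with DSC and ASSD.
#'
#' @param images,masks lists of labelled pairs.
#' @param trainer `function(trainImages, trainMasks)` returning a predictor
#'   `function(image) -> mask`.
#' @param k fold count (default 4).
#' @param seed shuffle seed.
#' @return data.frame of per-fold and mean DSC/ASSD.
#' @export
crossValidate <- function(images, masks, trainer, k = 4L, seed = 1L) {
  n <- length(images)
  if (n < k) stop("need at least as many samples as folds")
  if (length(masks) != n) stop("images and masks must pair up")
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  res <- data.frame(fold = seq_len(k), n_test = 0L, dsc = NA_real_,
                    assd = NA_real_)
  for (f in seq_len(k)) {
    tr <- which(fold != f); te <- which(fold == f)
    predict_ <- trainer(images[tr], masks[tr])
    ds <- as_ <- numeric(0)
    for (i in te) {
      p <- predict_(images[[i]])
      ds <- c(ds, dsc(p, masks[[i]]))
      as_ <- c(as_, tryCatch(assd(p, masks[[i]]), error = function(e)
        NA_real_))
    }
    res$n_test[f] <- length(te)
    res$dsc[f] <- mean(ds)
    res$assd[f] <- mean(as_)
  }
  rbind(res, data.frame(fold = NA, n_test = sum(res$n_test),
                        dsc = mean(res$dsc), assd = mean(res$assd)))
}
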