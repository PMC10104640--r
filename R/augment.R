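## Training-set augmentation: flips, dense small-angle rotations and
## photometric jitter, with image and mask transformed in lockstep.

#' Default augmentation rotation angles
#'
#' Rotations are taken at every 4 degrees across the circle, starting at 4
#' and stopping short of 360: 4, 8, ..., 356 -- 89 distinct angles.
#'
#' @return numeric vector of angles in degrees.
#' @export
augmentAngles <- function() seq(4, 356, by = 4)

.rotPair <- function(img, msk, angle, fill) {
  ri <- imageData(rotate(Image(img), angle, filter = "bilinear",
                         output.dim = dim(img), bg.col = fill))
  rm <- imageData(rotate(Image(msk), angle, filter = "none",
                         output.dim = dim(msk), bg.col = 0))
  list(img = pmin(pmax(ri, 0), 255), msk = (rm > 0.5) * 1L)
}

#' Augment a labelled image/mask pair
#'
#' Emits horizontal and vertical flips and rotations at every 4 degrees in
#' (4, 360) -- 89 angles, the 4-degree endpoint included -- with each
#' geometric transform applied identically to image and mask (the mask with
#' nearest-neighbour resampling, so it stays binary). Random contrast and
#' brightness jitter is applied to the image only. Rotation fill uses the
#' image's median background so empty corners do not mimic vessels.
#'
#' @param image [GrayImage-class] or matrix (0-255).
#' @param mask [VesselMask-class] or 0/1 matrix of the same shape.
#' @param seed RNG seed for the photometric jitter.
#' @param angles rotation angles in degrees (default [augmentAngles()]).
#' @param flips include horizontal/vertical flips (default TRUE).
#' @param jitter apply contrast/brightness jitter to the images.
#' @return list of `list(image, mask, transform)` entries; `transform` is a
#'   label such as `"rot_12"` or `"flip_h"`.
#' @export
augmentPairs <- function(image, mask, seed = 1L, angles = augmentAngles(),
                         flips = TRUE, jitter = TRUE) {
  img <- if (is(image, "GrayImage")) image@.Data else as.matrix(image)
  msk <- .maskMat(mask)
  if (!identical(dim(img), dim(msk)))
    stop("image and mask differ in shape")
  set.seed(seed)
  fill <- median(img[msk == 0L])
  out <- list()
  emit <- function(i, m, label) {
    if (jitter) {
      gain <- runif(1, 0.9, 1.1)
      bias <- runif(1, -10, 10)
      i <- pmin(pmax(i * gain + bias, 0), 255)
    }
    out[[length(out) + 1L]] <<- list(image = i, mask = m, transform = label)
  }
  if (flips) {
    emit(img[nrow(img):1, , drop = FALSE], msk[nrow(msk):1, , drop = FALSE],
         "flip_v")
    emit(img[, ncol(img):1, drop = FALSE], msk[, ncol(msk):1, drop = FALSE],
         "flip_h")
  }
  for (a in angles) {
    r <- .rotPair(img, msk, a, fill)
    emit(r$img, r$msk, paste0("rot_", a))
  }
  out
}
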