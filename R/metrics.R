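## Segmentation accuracy metrics: Dice similarity coefficient and average
## symmetric surface distance.

.maskMat <- function(x) {
  m <- if (is(x, "VesselMask") || is(x, "SkeletonMatrix")) x@.Data else
    as.matrix(x)
  storage.mode(m) <- "integer"
  m
}

#' Dice similarity coefficient
#'
#' Pixel-level overlap 2|A∩B| / (|A|+|B|) between a predicted and a
#' reference mask. Two empty masks are defined to agree perfectly (DSC 1).
#'
#' @param pred,truth [VesselMask-class] objects or 0/1 matrices of equal
#'   shape.
#' @return a fraction in [0, 1]; symmetric in its arguments.
#' @export
dsc <- function(pred, truth) {
  a <- .maskMat(pred); b <- .maskMat(truth)
  if (!identical(dim(a), dim(b))) stop("masks differ in shape")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

# boundary pixels: foreground with at least one background 4-neighbour
# (pixels beyond the raster count as background)
.boundary <- function(m) {
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(0L, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  inner <- pad[2:(H + 1), 2:(W + 1)]
  nb4 <- pad[1:H, 2:(W + 1)] + pad[3:(H + 2), 2:(W + 1)] +
         pad[2:(H + 1), 1:W] + pad[2:(H + 1), 3:(W + 2)]
  (inner == 1L) & (nb4 < 4L)
}

#' Average symmetric surface distance
#'
#' Mean, pooled over both masks' boundary pixels, of each boundary pixel's
#' Euclidean distance to the nearest boundary pixel of the other mask.
#' Boundaries are foreground pixels with at least one background
#' 4-neighbour. Undefined (error) when either mask is empty.
#'
#' @inheritParams dsc
#' @return distance in pixels (>= 0); 0 iff the boundaries coincide.
#' @export
assd <- function(pred, truth) {
  a <- .maskMat(pred); b <- .maskMat(truth)
  if (!identical(dim(a), dim(b))) stop("masks differ in shape")
  if (sum(a) == 0 || sum(b) == 0)
    stop("ASSD is undefined for an empty mask")
  ba <- .boundary(a); bb <- .boundary(b)
  # distance of every pixel to the nearest boundary pixel of each mask
  da <- imageData(distmap(Image(1 - ba)))
  db <- imageData(distmap(Image(1 - bb)))
  (sum(db[ba]) + sum(da[bb])) / (sum(ba) + sum(bb))
}
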