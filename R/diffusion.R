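## Extravascular drug diffusion: radial fluorescence profiles at selected
## vessel locations, diffusion depths D(n%), coverage areas and the in
## vitro-in vivo correlation.

#' Radial fluorescence profile outside a vessel wall
#'
#' @slot location diameter-class label (L1: 800-1000, L2: 600-800,
#'   L3: 400-600, L4: 200-400 um; NA outside these classes).
#' @slot distUm sampled distances from the vessel wall (um, increasing).
#' @slot gray raw grayscale samples along the ray.
#' @slot graySmooth 3-sample moving-average smoothed samples.
#' @slot G0 grayscale adjacent to the wall (mean of the first 3 samples).
#' @slot truncated TRUE when the ray left the image before `rayLengthUm`.
#' @slot pixelPitch um per pixel.
#' @export
setClass("DiffusionProfile",
         representation(location = "character", distUm = "numeric",
                        gray = "numeric", graySmooth = "numeric",
                        G0 = "numeric", truncated = "logical",
                        pixelPitch = "numeric"))

setMethod("show", "DiffusionProfile", function(object) {
  cat(sprintf(paste0("DiffusionProfile (%s): %d samples to %.0f um, ",
                     "G0 = %.1f%s\n"),
              object@location, length(object@distUm),
              max(object@distUm), object@G0,
              if (object@truncated) " (truncated)" else ""))
})

.bilinear <- function(img, y, x) {
  H <- nrow(img); W <- ncol(img)
  y <- pmin(pmax(y, 1), H); x <- pmin(pmax(x, 1), W)
  y0 <- pmin(floor(y), H - 1); x0 <- pmin(floor(x), W - 1)
  fy <- y - y0; fx <- x - x0
  img[cbind(y0, x0)] * (1 - fy) * (1 - fx) +
    img[cbind(y0 + 1, x0)] * fy * (1 - fx) +
    img[cbind(y0, x0 + 1)] * (1 - fy) * fx +
    img[cbind(y0 + 1, x0 + 1)] * fy * fx
}

.smooth3 <- function(v) {
  n <- length(v)
  if (n < 3) return(v)
  out <- v
  out[2:(n - 1)] <- (v[1:(n - 2)] + v[2:(n - 1)] + v[3:n]) / 3
  out[1] <- mean(v[1:2]); out[n] <- mean(v[(n - 1):n])
  out
}

.locationLabel <- function(diameterUm) {
  if (is.na(diameterUm)) return(NA_character_)
  if (diameterUm >= 800 && diameterUm <= 1000) "L1"
  else if (diameterUm >= 600 && diameterUm < 800) "L2"
  else if (diameterUm >= 400 && diameterUm < 600) "L3"
  else if (diameterUm >= 200 && diameterUm < 400) "L4"
  else NA_character_
}

#' Extract an extravascular fluorescence profile
#'
#' Casts a ray perpendicular to the local vessel direction at `anchor`,
#' starting at the vessel wall (the first point where the interpolated mask
#' falls below 0.5) and sampling the fluorescent channel at half-pixel
#' steps outward. The grayscale adjacent to the wall, G0, is the mean of
#' the first three samples; the profile is additionally smoothed with a
#' 3-sample moving average for threshold searches.
#'
#' @param fluor background-corrected fluorescent [GrayImage-class].
#' @param mask the vessel [VesselMask-class].
#' @param anchor `c(y, x)` skeleton pixel inside the vessel.
#' @param rayLengthUm maximum sampling distance beyond the wall (um).
#' @param pixelPitch um per pixel.
#' @param side +1 or -1: which side of the vessel to probe.
#' @param skeleton optional [SkeletonMatrix-class]; when supplied, the
#'   local direction is estimated from skeleton pixels near the anchor,
#'   otherwise from the mask neighbourhood.
#' @param stepPx ray sampling step in pixels (default 0.25).
#' @param noiseFloor minimum acceptable G0.
#' @return a [DiffusionProfile-class].
#' @export
extractProfile <- function(fluor, mask, anchor, rayLengthUm = 1000,
                           pixelPitch = 10, side = 1, skeleton = NULL,
                           stepPx = 0.25, noiseFloor = 1) {
  img <- if (is(fluor, "GrayImage")) fluor@.Data else as.matrix(fluor)
  m <- .maskMat(mask)
  H <- nrow(m); W <- ncol(m)
  ay <- anchor[1]; ax <- anchor[2]
  if (m[ay, ax] != 1L) stop("anchor must lie inside the vessel mask")
  # local direction: principal axis of nearby skeleton (or mask) pixels
  win <- 6L
  rr <- max(1, ay - win):min(H, ay + win)
  cc <- max(1, ax - win):min(W, ax + win)
  ref <- if (!is.null(skeleton)) .maskMat(skeleton)[rr, cc, drop = FALSE]
         else m[rr, cc, drop = FALSE]
  pts <- which(ref == 1L, arr.ind = TRUE)
  if (nrow(pts) < 2) stop("cannot estimate a local vessel direction")
  pts <- sweep(pts, 2, colMeans(pts))
  ev <- eigen(crossprod(pts) / nrow(pts), symmetric = TRUE)$vectors[, 1]
  perp <- c(-ev[2], ev[1]) * sign(side)
  # walk to the wall, then refine the 0.5-crossing by bisection
  t <- 0
  repeat {
    t <- t + stepPx
    y <- ay + t * perp[1]; x <- ax + t * perp[2]
    if (y < 1 || y > H || x < 1 || x > W)
      stop("ray left the image before reaching the vessel wall")
    if (.bilinear(m + 0, y, x) < 0.5) break
  }
  lo <- t - stepPx; hi <- t
  for (it in 1:6) {
    mid <- (lo + hi) / 2
    v <- .bilinear(m + 0, ay + mid * perp[1], ax + mid * perp[2])
    if (v < 0.5) hi <- mid else lo <- mid
  }
  w0 <- (lo + hi) / 2
  nStep <- floor(rayLengthUm / (stepPx * pixelPitch))
  ts <- w0 + stepPx * (0:nStep)
  ys <- ay + ts * perp[1]; xs <- ax + ts * perp[2]
  inside <- ys >= 1 & ys <= H & xs >= 1 & xs <= W
  truncated <- !all(inside)
  ys <- ys[inside]; xs <- xs[inside]
  g <- .bilinear(img, ys, xs)
  if (length(g) < 3) stop("profile too short; increase rayLengthUm")
  distUm <- (seq_along(g) - 1) * stepPx * pixelPitch
  G0 <- mean(g[1:3])
  if (G0 < noiseFloor)
    stop("wall-adjacent grayscale (", signif(G0, 3),
         ") is below the noise floor")
  dia <- tryCatch(pixelDiameter(c(ay, ax), VesselMask(m)) * pixelPitch,
                  error = function(e) NA_real_)
  new("DiffusionProfile",
      location = .locationLabel(dia), distUm = distUm, gray = g,
      graySmooth = .smooth3(g), G0 = G0, truncated = truncated,
      pixelPitch = pixelPitch)
}

#' Extravascular diffusion depth D(n\%)
#'
#' The largest distance at which the smoothed profile still reaches n\% of
#' the wall-adjacent grayscale G0, with linear interpolation at the
#' crossing. Profiles that never fall below the threshold return the ray
#' length with attribute `censored = TRUE`. D(n\%) is non-increasing in n.
#'
#' @param profile a [DiffusionProfile-class].
#' @param nPercent threshold percentage in (0, 100].
#' @return depth in micrometres with a logical `censored` attribute.
#' @export
diffusionDepth <- function(profile, nPercent) {
  if (nPercent <= 0 || nPercent > 100)
    stop("nPercent must be in (0, 100]")
  g <- profile@graySmooth
  x <- profile@distUm
  thr <- nPercent / 100 * profile@G0
  above <- g >= thr
  if (!any(above)) return(structure(0, censored = FALSE))
  i <- max(which(above))
  if (i == length(g))
    return(structure(x[length(x)], censored = TRUE))
  # interpolate the crossing between samples i and i+1
  f <- (g[i] - thr) / (g[i] - g[i + 1])
  structure(x[i] + f * (x[i + 1] - x[i]), censored = FALSE)
}

#' Background-correct a fluorescent image
#'
#' Subtracts a pre-injection reference frame when available, otherwise the
#' modal grayscale (the most frequent rounded intensity), clamping at 0.
#'
#' @param fluor [GrayImage-class] or matrix.
#' @param reference optional pre-injection frame.
#' @return corrected matrix (not clipped above).
#' @export
correctBackground <- function(fluor, reference = NULL) {
  img <- if (is(fluor, "GrayImage")) fluor@.Data else as.matrix(fluor)
  if (!is.null(reference)) {
    ref <- if (is(reference, "GrayImage")) reference@.Data else
      as.matrix(reference)
    if (!identical(dim(ref), dim(img))) stop("reference shape mismatch")
    return(pmax(img - ref, 0))
  }
  tab <- table(round(img))
  mode_ <- as.numeric(names(tab)[which.max(tab)])
  pmax(img - mode_, 0)
}

#' Drug-coverage areas
#'
#' Signal pixels are those with background-corrected grayscale >= 1 (on the
#' 0-255 scale); they are split by the vessel mask into intravascular and
#' extravascular areas. Total = intra + extra by construction.
#'
#' @param fluor fluorescent [GrayImage-class] or matrix.
#' @param mask vessel [VesselMask-class].
#' @param background scalar background level to subtract, or a reference
#'   frame; 0 for an already-corrected image.
#' @param pixelPitch um per pixel (for um^2 areas).
#' @return one-row data.frame: total/intra/extra areas in px^2 and um^2,
#'   and the extravascular/intravascular ratio (0 when intra is 0).
#' @export
coverage <- function(fluor, mask, background = 0, pixelPitch = 10) {
  img <- if (is(fluor, "GrayImage")) fluor@.Data else as.matrix(fluor)
  m <- .maskMat(mask)
  corr <- if (length(background) == 1) pmax(img - background, 0)
          else correctBackground(img, background)
  sig <- corr >= 1
  intra <- sum(sig & m == 1L)
  extra <- sum(sig & m == 0L)
  a <- pixelPitch^2
  data.frame(total_px = intra + extra, intra_px = intra, extra_px = extra,
             total_um2 = (intra + extra) * a, intra_um2 = intra * a,
             extra_um2 = extra * a,
             ratio = if (intra > 0) extra / intra else 0)
}

#' Time-layered coverage overlay
#'
#' Labels every pixel with the earliest and the latest time point at which
#' signal is present, and tabulates coverage areas normalised to the first
#' time point.
#'
#' @param fluors list of fluorescent frames (registered time series).
#' @param mask vessel [VesselMask-class].
#' @param background as in [coverage()].
#' @param times optional time labels.
#' @param pixelPitch um per pixel.
#' @return list with `earliest` and `latest` label matrices (0 = never) and
#'   a `table` of per-time areas with `area_ratio` vs the first time point.
#' @export
coverageOverlay <- function(fluors, mask, background = 0, times = NULL,
                            pixelPitch = 10) {
  if (!length(fluors)) stop("empty time series")
  if (is.null(times)) times <- seq_along(fluors) - 1
  m <- .maskMat(mask)
  earliest <- latest <- matrix(0L, nrow(m), ncol(m))
  tab <- list()
  for (i in seq_along(fluors)) {
    img <- if (is(fluors[[i]], "GrayImage")) fluors[[i]]@.Data else
      as.matrix(fluors[[i]])
    if (!identical(dim(img), dim(m)))
      stop("frame ", i, " shape mismatch")
    corr <- if (length(background) == 1) pmax(img - background, 0)
            else correctBackground(img, background)
    sig <- corr >= 1
    earliest[sig & earliest == 0L] <- i
    latest[sig] <- i
    tab[[i]] <- cbind(time = times[i],
                      coverage(img, VesselMask(m), background, pixelPitch))
  }
  tab <- do.call(rbind, tab)
  tab$area_ratio <- if (tab$total_px[1] > 0)
    tab$total_px / tab$total_px[1] else
    ifelse(tab$total_px == 0, 0, NA)
  list(earliest = earliest, latest = latest, table = tab)
}

#' In vitro-in vivo correlation fit
#'
#' @slot pairs the fitted (g_ratio, c_ratio) pairs with residuals.
#' @slot slope,intercept,r2 ordinary least squares results of the in vivo
#'   concentration ratio C_n/C_0 on the in vitro grayscale ratio G_n/G_0.
#' @export
setClass("IvivcFit",
         representation(pairs = "data.frame", slope = "numeric",
                        intercept = "numeric", r2 = "numeric"))

setMethod("show", "IvivcFit", function(object) {
  cat(sprintf("IvivcFit: slope %.3f, intercept %.3f, R^2 %.3f (n = %d)\n",
              object@slope, object@intercept, object@r2,
              nrow(object@pairs)))
})

#' Fit the in vitro-in vivo correlation
#'
#' Ordinary least squares of the in vivo concentration ratio C_n/C_0 on the
#' in vitro fluorescence ratio G_n/G_0 across matched depths and time
#' points.
#'
#' @param pairs data.frame with columns `g_ratio` and `c_ratio` (>= 3
#'   rows).
#' @return an [IvivcFit-class].
#' @export
ivivcFit <- function(pairs) {
  stopifnot(all(c("g_ratio", "c_ratio") %in% names(pairs)))
  if (nrow(pairs) < 3) stop("need at least 3 pairs")
  if (sd(pairs$g_ratio) == 0) stop("zero variance in G ratios")
  fit <- lm(c_ratio ~ g_ratio, data = pairs)
  pairs$residual <- unname(fit$residuals)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits are fine
  new("IvivcFit", pairs = pairs,
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      r2 = r2)
}
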