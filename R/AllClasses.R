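#' @include vasq-package.R
NULL

## ---------------------------------------------------------------- rasters

#' Grayscale image
#'
#' A 2D intensity raster on the 8-bit scale [0, 255]. Pixels are stored as
#' doubles so that synthetic renderings keep full precision; quantisation to
#' integer levels happens only when an image is written to disk. Matrix rows
#' are image rows (y), columns are x; indices are 1-based.
#'
#' @slot .Data numeric matrix of intensities in [0, 255].
#' @slot channel either \code{"bright_field"} or \code{"fluorescent"}.
#' @export
setClass("GrayImage", contains = "matrix",
         representation(channel = "character"),
         prototype(channel = "bright_field"))

setValidity("GrayImage", function(object) {
  v <- object@.Data
  if (!is.numeric(v) || length(dim(v)) != 2)
    return("pixels must be a 2D numeric matrix")
  if (any(!is.finite(v)) || min(v) < 0 || max(v) > 255)
    return("intensities must be finite and within [0, 255]")
  if (!object@channel %in% c("bright_field", "fluorescent"))
    return("channel must be 'bright_field' or 'fluorescent'")
  TRUE
})

#' Construct a GrayImage
#'
#' @param pixels numeric matrix in [0, 255].
#' @param channel `"bright_field"` (default) or `"fluorescent"`.
#' @return a [GrayImage-class] object.
#' @export
GrayImage <- function(pixels, channel = "bright_field") {
  new("GrayImage", as.matrix(pixels), channel = channel)
}

#' Binary vessel mask
#'
#' Same shape as its source image; 1 marks drug-containing vessel pixels.
#'
#' @slot .Data integer matrix of 0/1.
#' @export
setClass("VesselMask", contains = "matrix")

setValidity("VesselMask", function(object) {
  v <- object@.Data
  if (length(dim(v)) != 2) return("mask must be a 2D matrix")
  if (!all(v %in% c(0L, 1L))) return("mask values must be 0/1")
  TRUE
})

#' Construct a VesselMask
#' @param pixels matrix coercible to 0/1.
#' @return a [VesselMask-class] object.
#' @export
VesselMask <- function(pixels) {
  m <- as.matrix(pixels)
  storage.mode(m) <- "integer"
  new("VesselMask", m)
}

#' Single-pixel-wide skeleton
#'
#' Binary raster produced by [skeletonize()]: no 2x2 block is fully set and
#' every skeleton pixel lies inside the originating mask.
#'
#' @slot .Data integer matrix of 0/1.
#' @export
setClass("SkeletonMatrix", contains = "matrix")

setValidity("SkeletonMatrix", function(object) {
  v <- object@.Data
  if (length(dim(v)) != 2) return("skeleton must be a 2D matrix")
  if (!all(v %in% c(0L, 1L))) return("skeleton values must be 0/1")
  if (nrow(v) > 1 && ncol(v) > 1) {
    blk <- v[-nrow(v), -ncol(v)] + v[-1, -ncol(v)] +
           v[-nrow(v), -1] + v[-1, -1]
    if (any(blk == 4)) return("skeleton contains a fully set 2x2 block")
  }
  TRUE
})

#' Construct a SkeletonMatrix
#' @param pixels matrix coercible to 0/1.
#' @return a [SkeletonMatrix-class] object.
#' @export
SkeletonMatrix <- function(pixels) {
  m <- as.matrix(pixels)
  storage.mode(m) <- "integer"
  new("SkeletonMatrix", m)
}

## ----------------------------------------------------------------- graph

#' Vessel graph
#'
#' Topology of a vascular tree: nodes are the root, bifurcations and leaves;
#' edges are the branch sections between them, each carrying its ordered
#' pixel path, length (pixel count), mean diameter and, once assigned, a
#' hierarchical level P1--P5.
#'
#' @slot nodes data.frame with columns `id`, `y`, `x`, `kind`
#'   (`"root"`, `"bifurcation"` or `"leaf"`).
#' @slot edges data.frame with columns `id`, `from`, `to`, `length_px`,
#'   `mean_diameter_px`, `level` (integer, `NA` = unassigned).
#' @slot paths list of integer matrices (columns y, x), one ordered pixel
#'   path per edge, endpoints included.
#' @slot dim integer raster dimensions the coordinates refer to (may be
#'   `NA` for abstract graphs).
#' @slot pixelPitch micrometres per pixel.
#' @export
setClass("VesselGraph",
         representation(nodes = "data.frame", edges = "data.frame",
                        paths = "list", dim = "integer",
                        pixelPitch = "numeric"),
         prototype(dim = c(NA_integer_, NA_integer_), pixelPitch = 10))

setValidity("VesselGraph", function(object) {
  nd <- object@nodes; ed <- object@edges
  need_n <- c("id", "y", "x", "kind"); need_e <- c("id", "from", "to",
              "length_px", "mean_diameter_px", "level")
  if (!all(need_n %in% names(nd))) return("nodes lack required columns")
  if (!all(need_e %in% names(ed))) return("edges lack required columns")
  if (anyDuplicated(nd$id)) return("duplicate node ids")
  if (nrow(ed)) {
    if (!all(c(ed$from, ed$to) %in% nd$id))
      return("edge endpoints must be node ids")
    if (any(ed$length_px <= 0)) return("edge lengths must be positive")
    if (length(object@paths) != nrow(ed))
      return("one pixel path required per edge")
    lv <- ed$level[!is.na(ed$level)]
    if (length(lv) && (any(lv < 1) || any(lv > 5)))
      return("assigned levels must be in 1..5")
  }
  if (!all(nd$kind %in% c("root", "bifurcation", "leaf")))
    return("node kind must be root/bifurcation/leaf")
  TRUE
})

#' Construct a VesselGraph
#'
#' @param nodes,edges,paths see [VesselGraph-class].
#' @param dim raster dimensions (rows, cols).
#' @param pixelPitch micrometres per pixel.
#' @return a [VesselGraph-class] object.
#' @export
VesselGraph <- function(nodes, edges, paths,
                        dim = c(NA_integer_, NA_integer_), pixelPitch = 10) {
  edges$level <- as.integer(edges$level)
  new("VesselGraph", nodes = nodes, edges = edges, paths = paths,
      dim = as.integer(dim), pixelPitch = pixelPitch)
}

#' @rdname VesselGraph-class
#' @param graph a `VesselGraph`.
#' @export
graphNodes <- function(graph) graph@nodes

#' @rdname VesselGraph-class
#' @export
graphEdges <- function(graph) graph@edges

#' @rdname VesselGraph-class
#' @export
edgePaths <- function(graph) graph@paths

## --------------------------------------------------------------- phantom

#' Specification of a synthetic vascular phantom
#'
#' All geometric quantities are in micrometres and converted internally via
#' `pixelPitch`. Per-level vectors are indexed by branching generation
#' (1 = inlet trunk). Defaults emulate a stereomicroscopy field of a
#' perfused hepatic portal tree: generation diameters taper from about
#' 900 um down to 55 +/- 7 um, the inlet carries the injected drug
#' concentration, and intravascular grayscale follows the modified
#' Beer-Lambert attenuation A = epsilon*log10(c*d) + k relative to the
#' background level.
#'
#' @slot imageHeight,imageWidth canvas size in pixels.
#' @slot pixelPitch micrometres per pixel (default 10).
#' @slot nLevels number of branching generations (0 = background only).
#' @slot branchingFactor children per bifurcation (recycled per level).
#' @slot diameterMeanUm,diameterSdUm per-generation tube diameter (um).
#' @slot lengthMeanUm,lengthSdUm per-generation branch length (um).
#' @slot trunkConcentration injected drug concentration, mg/mL.
#' @slot concentrationDecay multiplicative concentration factor applied at
#'   each bifurcation downstream of the source edges, in (0, 1].
#' @slot haloScaleUm radial decay length of the extravascular fluorescent
#'   halo (um).
#' @slot noiseSdGray additive Gaussian grayscale noise (0 = noise-free).
#' @slot backgroundGray bright-field background grayscale G_B.
#' @slot fluorWallGray fluorescent amplitude at the vessel wall.
#' @slot fluorBackgroundGray fluorescent background level.
#' @slot epsilon,k forward Beer-Lambert parameters.
#' @slot seed RNG seed; fixes the whole bundle bit-for-bit.
#' @export
setClass("PhantomSpec",
         representation(imageHeight = "integer", imageWidth = "integer",
                        pixelPitch = "numeric", nLevels = "integer",
                        branchingFactor = "integer",
                        diameterMeanUm = "numeric", diameterSdUm = "numeric",
                        lengthMeanUm = "numeric", lengthSdUm = "numeric",
                        trunkConcentration = "numeric",
                        concentrationDecay = "numeric",
                        haloScaleUm = "numeric", noiseSdGray = "numeric",
                        backgroundGray = "numeric", fluorWallGray = "numeric",
                        fluorBackgroundGray = "numeric",
                        epsilon = "numeric", k = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  s <- object
  if (s@imageHeight < 1 || s@imageWidth < 1) return("image size must be >= 1")
  if (s@pixelPitch <= 0) return("pixel pitch must be positive")
  if (s@nLevels < 0 || s@nLevels > 7) return("nLevels must be in 0..7")
  if (any(s@branchingFactor < 1)) return("branching factor must be >= 1")
  if (s@nLevels > 0) {
    if (length(s@diameterMeanUm) < s@nLevels ||
        length(s@lengthMeanUm) < s@nLevels)
      return("diameter/length vectors must cover all levels")
    d <- s@diameterMeanUm[seq_len(s@nLevels)]
    if (any(d <= 0)) return("diameters must be positive")
    if (s@nLevels > 1 && any(diff(d) >= 0))
      return("diameters must strictly decrease with level")
    if (any(s@lengthMeanUm[seq_len(s@nLevels)] <= 0))
      return("lengths must be positive")
  }
  if (s@trunkConcentration < 0) return("concentration must be >= 0")
  if (s@concentrationDecay <= 0 || s@concentrationDecay > 1)
    return("concentrationDecay must be in (0, 1]")
  if (s@haloScaleUm <= 0) return("haloScaleUm must be positive")
  if (s@noiseSdGray < 0) return("noiseSdGray must be >= 0")
  TRUE
})

#' Construct a PhantomSpec
#'
#' @param imageHeight,imageWidth canvas size, pixels.
#' @param pixelPitch um per pixel.
#' @param nLevels branching generations.
#' @param branchingFactor children per bifurcation.
#' @param diameterMeanUm,diameterSdUm per-generation diameters (um).
#' @param lengthMeanUm,lengthSdUm per-generation branch lengths (um).
#' @param trunkConcentration injected concentration, mg/mL.
#' @param concentrationDecay per-bifurcation concentration factor.
#' @param haloScaleUm halo decay length, um.
#' @param noiseSdGray additive grayscale noise SD.
#' @param backgroundGray bright-field background G_B.
#' @param fluorWallGray,fluorBackgroundGray fluorescent wall amplitude and
#'   background level.
#' @param epsilon,k forward attenuation parameters.
#' @param seed RNG seed.
#' @return a [PhantomSpec-class] object.
#' @export
PhantomSpec <- function(imageHeight = 1024L, imageWidth = 1024L,
                        pixelPitch = 10,
                        nLevels = 5L, branchingFactor = 2L,
                        diameterMeanUm = c(900, 400, 100, 64, 55, 40, 30),
                        diameterSdUm = c(60, 12, 15, 8, 7, 5, 4),
                        lengthMeanUm = c(5000, 2200, 1500, 1000, 700,
                                         500, 400),
                        lengthSdUm = lengthMeanUm * 0.05,
                        trunkConcentration = 5,
                        concentrationDecay = 0.8,
                        haloScaleUm = 100, noiseSdGray = 5,
                        backgroundGray = 220, fluorWallGray = 180,
                        fluorBackgroundGray = 10,
                        epsilon = 0.249, k = 0, seed = 1L) {
  new("PhantomSpec", imageHeight = as.integer(imageHeight),
      imageWidth = as.integer(imageWidth), pixelPitch = pixelPitch,
      nLevels = as.integer(nLevels),
      branchingFactor = as.integer(branchingFactor),
      diameterMeanUm = diameterMeanUm, diameterSdUm = diameterSdUm,
      lengthMeanUm = lengthMeanUm, lengthSdUm = lengthSdUm,
      trunkConcentration = trunkConcentration,
      concentrationDecay = concentrationDecay,
      haloScaleUm = haloScaleUm, noiseSdGray = noiseSdGray,
      backgroundGray = backgroundGray, fluorWallGray = fluorWallGray,
      fluorBackgroundGray = fluorBackgroundGray,
      epsilon = epsilon, k = k, seed = as.integer(seed))
}

#' Synthetic phantom bundle
#'
#' A rendered image pair plus the complete ground truth needed to validate
#' every downstream stage.
#'
#' @slot brightField,fluorescent [GrayImage-class] channels.
#' @slot truthMask [VesselMask-class] rasterised tree.
#' @slot truthGraph [VesselGraph-class] with exact diameters and levels.
#' @slot truthConcentration numeric, mg/mL per truth-graph edge.
#' @slot spec the generating [PhantomSpec-class].
#' @export
setClass("PhantomBundle",
         representation(brightField = "GrayImage", fluorescent = "GrayImage",
                        truthMask = "VesselMask", truthGraph = "VesselGraph",
                        truthConcentration = "numeric", spec = "PhantomSpec"))

## ------------------------------------------------------------ photometry

#' Beer-Lambert calibration model
#'
#' Light attenuation A = log10(G_B/G) regressed on log10(c*d): slope is the
#' attenuation coefficient epsilon, intercept the attenuation-independent
#' offset k.
#'
#' @slot epsilon attenuation coefficient (slope).
#' @slot k attenuation-independent offset (intercept).
#' @slot epsilonSE standard error of the slope (NA when not fitted).
#' @slot r2 coefficient of determination (NA when not fitted).
#' @slot GB background grayscale used for attenuation.
#' @export
setClass("CalibrationModel",
         representation(epsilon = "numeric", k = "numeric",
                        epsilonSE = "numeric", r2 = "numeric",
                        GB = "numeric"))

setValidity("CalibrationModel", function(object) {
  if (object@epsilon <= 0) return("epsilon must be > 0 for absorbing dyes")
  if (!is.na(object@r2) && (object@r2 < 0 || object@r2 > 1))
    return("R^2 must be in [0, 1]")
  TRUE
})

#' Construct a CalibrationModel
#'
#' @param epsilon attenuation coefficient; the experimentally obtained
#'   default is 0.249.
#' @param k offset (default 0).
#' @param GB background grayscale.
#' @param epsilonSE,r2 fit diagnostics.
#' @return a [CalibrationModel-class] object.
#' @export
CalibrationModel <- function(epsilon = 0.249, k = 0, GB = 220,
                             epsilonSE = NA_real_, r2 = NA_real_) {
  new("CalibrationModel", epsilon = epsilon, k = k, GB = GB,
      epsilonSE = epsilonSE, r2 = r2)
}

#' Per-edge concentration map
#'
#' @slot map data.frame with columns `edge_id`, `level`, `G_t`, `d_t_px`,
#'   `c_t`, `c_rel` (c_t/c0) and `clipped`.
#' @slot c0 injected concentration (mg/mL).
#' @slot sourceEdges integer ids of the source edges.
#' @slot GS,dS source-edge mean grayscale and mean diameter (px).
#' @export
setClass("ConcentrationMap",
         representation(map = "data.frame", c0 = "numeric",
                        sourceEdges = "integer", GS = "numeric",
                        dS = "numeric"))

## --------------------------------------------------------------- show

setMethod("show", "GrayImage", function(object) {
  cat(sprintf("GrayImage (%s): %d x %d px, range [%.1f, %.1f]\n",
              object@channel, nrow(object), ncol(object),
              min(object@.Data), max(object@.Data)))
})

setMethod("show", "VesselMask", function(object) {
  cat(sprintf("VesselMask: %d x %d px, %d foreground (%.2f%%)\n",
              nrow(object), ncol(object), sum(object@.Data),
              100 * mean(object@.Data)))
})

setMethod("show", "SkeletonMatrix", function(object) {
  cat(sprintf("SkeletonMatrix: %d x %d px, %d skeleton pixels\n",
              nrow(object), ncol(object), sum(object@.Data)))
})

setMethod("show", "VesselGraph", function(object) {
  lv <- object@edges$level
  cat(sprintf(paste0("VesselGraph: %d nodes (%d bifurcations, %d leaves),",
                     " %d edges, %s\n"),
              nrow(object@nodes),
              sum(object@nodes$kind == "bifurcation"),
              sum(object@nodes$kind == "leaf"),
              nrow(object@edges),
              if (all(is.na(lv))) "levels unassigned" else
                paste0("levels P", paste(sort(unique(lv[!is.na(lv)])),
                                         collapse = "/P"))))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(paste0("PhantomSpec: %dx%d px @ %.1f um/px, %d levels, ",
                     "branching %s, c0 = %.2f mg/mL, seed %d\n"),
              object@imageHeight, object@imageWidth, object@pixelPitch,
              object@nLevels,
              paste(object@branchingFactor, collapse = "/"),
              object@trunkConcentration, object@seed))
})

setMethod("show", "PhantomBundle", function(object) {
  cat("PhantomBundle\n")
  cat("  "); show(object@brightField)
  cat("  "); show(object@truthMask)
  cat("  "); show(object@truthGraph)
})

setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf("CalibrationModel: epsilon = %.4f, k = %.4f, G_B = %.1f",
              object@epsilon, object@k, object@GB))
  if (!is.na(object@r2)) cat(sprintf(", R^2 = %.4f", object@r2))
  cat("\n")
})

setMethod("show", "ConcentrationMap", function(object) {
  cat(sprintf(paste0("ConcentrationMap: %d edges (levels <= %s), c0 = %.2f",
                     " mg/mL, %d clipped\n"),
              nrow(object@map),
              max(object@map$level, na.rm = TRUE),
              object@c0, sum(object@map$clipped)))
})
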