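## Intravascular drug photometry. The modified Beer-Lambert model relates
## light attenuation A = log10(G_B/G) to log10(c*d): A = eps*log10(c*d) + k.
## Its edge-to-edge ratio form, log10(G_t/G_s) = eps*[log10(c_s/c_t) +
## log10(d_s/d_t)], propagates the known source-edge concentration to every
## target edge (the offset k cancels in the ratio).

#' Fit the attenuation calibration
#'
#' Ordinary least squares of A = log10(G_B/G) on log10(c*d) over
#' calibration samples (known concentration, channel size, measured
#' grayscale), as acquired from a microfluidic channel array. Saturated
#' samples (G = 0) are excluded with a warning.
#'
#' @param samples data.frame with columns `c` (mg/mL), `d` (channel
#'   diameter; any fixed unit) and `G` (measured grayscale).
#' @param GB background grayscale.
#' @return a [CalibrationModel-class] with slope `epsilon`, intercept `k`,
#'   slope standard error and R^2.
#' @export
fitCalibration <- function(samples, GB) {
  stopifnot(all(c("c", "d", "G") %in% names(samples)))
  bad <- samples$G <= 0
  if (any(bad)) {
    warning(sum(bad), " saturated sample(s) with G <= 0 excluded")
    samples <- samples[!bad, , drop = FALSE]
  }
  if (nrow(samples) < 3) stop("need at least 3 usable calibration samples")
  x <- log10(samples$c * samples$d)
  if (length(unique(signif(x, 12))) < 2)
    stop("all samples share the same c*d; the fit is rank deficient")
  A <- log10(GB / samples$G)
  fit <- lm(A ~ x)
  sm <- suppressWarnings(summary(fit))  # noiseless fits are legitimate
  CalibrationModel(epsilon = unname(coef(fit)[2]),
                   k = unname(coef(fit)[1]), GB = GB,
                   epsilonSE = sm$coefficients[2, 2],
                   r2 = sm$r.squared)
}

#' Estimate the background grayscale of a bright-field image
#'
#' Median grayscale outside a 5-pixel dilation of the vessel mask.
#'
#' @param image [GrayImage-class] or matrix.
#' @param mask [VesselMask-class].
#' @return scalar G_B.
#' @export
estimateBackground <- function(image, mask) {
  img <- if (is(image, "GrayImage")) image@.Data else as.matrix(image)
  m <- .maskMat(mask)
  dil <- imageData(dilate(Image(m), makeBrush(11, "disc")))
  out <- img[dil == 0]
  if (!length(out)) stop("no background pixels outside the dilated mask")
  median(out)
}

# per-edge photometry: mean grayscale over the edge's skeleton path.
# Near a junction the path of one branch runs inside the lumen of its
# (wider, darker) neighbour for up to r/sin(theta) pixels, so path pixels
# lying within any neighbouring edge's tube (chord between its endpoint
# nodes, radius = half its mean diameter) are excluded from the average.
.edgePhotometry <- function(graph, bright, trim = TRUE) {
  img <- if (is(bright, "GrayImage")) bright@.Data else as.matrix(bright)
  ed <- graph@edges
  nd <- graph@nodes
  H <- nrow(img)
  ny <- nd$y[match(ed$from, nd$id)]; nx <- nd$x[match(ed$from, nd$id)]
  ty <- nd$y[match(ed$to, nd$id)]; tx <- nd$x[match(ed$to, nd$id)]
  G <- numeric(nrow(ed))
  for (i in seq_len(nrow(ed))) {
    p <- graph@paths[[i]]
    n <- nrow(p)
    keep <- rep(TRUE, n)
    if (trim && n > 2) {
      nbr <- which((ed$from %in% c(ed$from[i], ed$to[i]) |
                    ed$to %in% c(ed$from[i], ed$to[i])) & ed$id != ed$id[i])
      for (j in nbr) {
        vy <- ty[j] - ny[j]; vx <- tx[j] - nx[j]
        L2 <- vy * vy + vx * vx
        t <- if (L2 == 0) rep(0, n) else
          pmax(0, pmin(1, ((p[, 1] - ny[j]) * vy +
                           (p[, 2] - nx[j]) * vx) / L2))
        d2 <- (p[, 1] - ny[j] - t * vy)^2 + (p[, 2] - nx[j] - t * vx)^2
        keep <- keep & d2 > (ed$mean_diameter_px[j] / 2 + 1.5)^2
      }
      if (!any(keep)) keep[max(1L, round(n / 2))] <- TRUE
    }
    G[i] <- mean(img[(p[keep, 2] - 1L) * H + p[keep, 1]])
  }
  G
}

#' Propagate drug concentration along the vessel graph
#'
#' The source edges are the first edges extending from the root (the inlet
#' stub, when identified, is excluded); their mean grayscale G_s and mean
#' diameter d_s are computed, and the source concentration c_s equals the
#' injected concentration `c0`. Each target edge's concentration follows
#' from the ratio form of the attenuation model:
#' c_t = c_s * (d_s/d_t) * (G_s/G_t)^(1/epsilon).
#' Quantification is restricted to levels <= `maxLevel` (default 2: the
#' vascular trunk, where grayscale is least noise-affected). Values are
#' clipped to [0, cClip*c0] with clip events flagged; edges with
#' non-positive grayscale are skipped and flagged.
#'
#' @param graph a level-classified [VesselGraph-class] with a root node.
#' @param bright the bright-field [GrayImage-class].
#' @param calib a [CalibrationModel-class].
#' @param c0 injected drug concentration (mg/mL).
#' @param maxLevel highest branch level quantified (default 2).
#' @param cClip clip ceiling as a multiple of `c0` (default 2).
#' @param inletMargin border margin for inlet identification (px).
#' @param trim trim edge paths near junctions before averaging grayscale.
#' @param reference optional [ConcentrationMap-class] from the zero-time
#'   point: its source photometry (G_s, d_s, with c_s = c0) is reused so
#'   that later frames of a time series report concentrations relative to
#'   the injected state rather than to their own (already depleted)
#'   source edges.
#' @return a [ConcentrationMap-class].
#' @export
propagateConcentration <- function(graph, bright, calib, c0, maxLevel = 2,
                                   cClip = 2, inletMargin = 2, trim = TRUE,
                                   reference = NULL) {
  ed <- graph@edges
  if (!nrow(ed)) stop("graph has no edges")
  if (anyNA(ed$level)) stop("graph levels are unassigned; run ",
                            "classifyLevels() first")
  root <- graph@nodes$id[graph@nodes$kind == "root"]
  if (!length(root)) stop("graph has no root node")
  if (calib@epsilon <= 0) stop("calibration epsilon must be positive")
  G <- .edgePhotometry(graph, bright, trim = trim)
  inlet <- .findInlet(graph, root, inletMargin)
  src <- setdiff(ed$id[ed$from == root | ed$to == root],
                 if (is.na(inlet)) integer(0) else inlet)
  if (!length(src)) src <- ed$id[ed$from == root | ed$to == root]
  if (is.null(reference)) {
    GS <- mean(G[match(src, ed$id)])
    dS <- mean(ed$mean_diameter_px[match(src, ed$id)])
  } else {
    stopifnot(is(reference, "ConcentrationMap"))
    GS <- reference@GS
    dS <- reference@dS
    src <- reference@sourceEdges
  }
  sel <- which(ed$level <= maxLevel)
  Gt <- G[sel]
  dtv <- ed$mean_diameter_px[sel]
  ok <- Gt > 0
  ct <- rep(NA_real_, length(sel))
  ct[ok] <- c0 * (dS / dtv[ok]) * (GS / Gt[ok])^(1 / calib@epsilon)
  clipped <- !ok | ct > cClip * c0 | ct < 0
  ct <- pmin(cClip * c0, pmax(0, ct))
  new("ConcentrationMap",
      map = data.frame(edge_id = ed$id[sel], level = ed$level[sel],
                       G_t = Gt, d_t_px = dtv, c_t = ct,
                       c_rel = ct / c0, clipped = clipped),
      c0 = c0, sourceEdges = as.integer(src), GS = GS, dS = dS)
}

#' Residual-concentration time course
#'
#' Mean and SEM of the per-edge concentration over a fixed edge selection,
#' per time point, also expressed as a percentage of the injected
#' concentration.
#'
#' @param maps list of [ConcentrationMap-class] over time (registered
#'   series sharing a graph lineage).
#' @param edgeIds edges to average; defaults to the source edges of the
#'   first map (the main branches nearest the root).
#' @param times optional time labels.
#' @return data.frame with columns time, mean_ct, sem, pct_c0.
#' @export
concentrationTimecourse <- function(maps, edgeIds = NULL, times = NULL) {
  if (!length(maps)) stop("empty map sequence")
  if (is.null(edgeIds)) edgeIds <- maps[[1]]@sourceEdges
  if (!length(edgeIds)) stop("empty edge selection")
  if (is.null(times)) times <- seq_along(maps) - 1
  rows <- lapply(seq_along(maps), function(i) {
    m <- maps[[i]]@map
    v <- m$c_t[m$edge_id %in% edgeIds]
    v <- v[!is.na(v)]
    if (!length(v)) stop("edge selection matches no edges at time ", i)
    data.frame(time = times[i], mean_ct = mean(v),
               sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else 0,
               pct_c0 = 100 * mean(v) / maps[[i]]@c0)
  })
  do.call(rbind, rows)
}
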