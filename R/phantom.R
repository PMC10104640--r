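## Synthetic vascular phantoms: branching trees with level-dependent
## diameters, bright-field rendering through the forward Beer-Lambert model,
## fluorescent halos with exponential radial decay, and complete ground
## truth (mask, graph, levels, per-edge concentrations).

# linear (column-major) indices of pixels within diameter/2 of the segment
# (y0,x0)-(y1,x1); coordinates are 1-based pixel centers
.tubePixels <- function(H, W, y0, x0, y1, x1, dpx) {
  r <- dpx / 2
  rr <- max(1L, floor(min(y0, y1) - r)):min(H, ceiling(max(y0, y1) + r))
  cc <- max(1L, floor(min(x0, x1) - r)):min(W, ceiling(max(x0, x1) + r))
  if (!length(rr) || !length(cc)) return(integer(0))
  yy <- rep(rr, times = length(cc))
  xx <- rep(cc, each = length(rr))
  vy <- y1 - y0; vx <- x1 - x0
  L2 <- vy * vy + vx * vx
  t <- if (L2 == 0) 0 else pmax(0, pmin(1, ((yy - y0) * vy +
                                            (xx - x0) * vx) / L2))
  d2 <- (yy - y0 - t * vy)^2 + (xx - x0 - t * vx)^2
  sel <- d2 <= r * r
  (xx[sel] - 1L) * H + yy[sel]
}

# minimum distance between two segments, each optionally truncated to
# t in [ta, 1] / [tb, 1] of its parameterisation
.segSegDist <- function(a0, a1, b0, b1, ta = 0, tb = 0) {
  a0 <- a0 + ta * (a1 - a0)
  b0 <- b0 + tb * (b1 - b0)
  p2s <- function(p, s0, s1) {
    v <- s1 - s0; L2 <- sum(v * v)
    t <- if (L2 == 0) 0 else max(0, min(1, sum((p - s0) * v) / L2))
    sqrt(sum((p - s0 - t * v)^2))
  }
  cross <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) -
                             (a[2] - o[2]) * (b[1] - o[1])
  d1 <- cross(a0, a1, b0); d2 <- cross(a0, a1, b1)
  d3 <- cross(b0, b1, a0); d4 <- cross(b0, b1, a1)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(0)
  min(p2s(a0, b0, b1), p2s(a1, b0, b1), p2s(b0, a0, a1), p2s(b1, a0, a1))
}

# 8-connected Bresenham pixel path between two integer pixels, inclusive
.bresenham <- function(y0, x0, y1, x1) {
  dy <- abs(y1 - y0); dx <- abs(x1 - x0)
  sy <- sign(y1 - y0); sx <- sign(x1 - x0)
  n <- max(dy, dx) + 1L
  out <- matrix(0L, n, 2L)
  err <- dx - dy
  y <- y0; x <- x0
  for (i in seq_len(n)) {
    out[i, ] <- c(y, x)
    if (y == y1 && x == x1) { out <- out[seq_len(i), , drop = FALSE]; break }
    e2 <- 2L * err
    if (e2 > -dy) { err <- err - dy; x <- x + sx }
    if (e2 < dx)  { err <- err + dx; y <- y + sy }
  }
  out
}

.truncNorm <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  pmin(mean + 2.5 * sd, pmax(mean - 2.5 * sd, rnorm(n, mean, sd)))
}

# grow the branching tree; returns a data.frame of segments
.growTree <- function(spec) {
  H <- spec@imageHeight; W <- spec@imageWidth; pitch <- spec@pixelPitch
  nl <- spec@nLevels
  bf <- rep(spec@branchingFactor, length.out = max(1L, nl))
  segs <- data.frame(id = integer(0), parent = integer(0), gen = integer(0),
                     y0 = numeric(0), x0 = numeric(0), y1 = numeric(0),
                     x1 = numeric(0), angle = numeric(0), d_px = numeric(0),
                     d_um = numeric(0), conc = numeric(0))
  if (nl == 0L) return(segs)

  drawGeom <- function(gen) {
    L <- .truncNorm(1, spec@lengthMeanUm[gen], spec@lengthSdUm[gen]) / pitch
    d <- .truncNorm(1, spec@diameterMeanUm[gen], spec@diameterSdUm[gen]) /
      pitch
    if (d < 1) stop("phantom level ", gen,
                    " requests a sub-pixel (effectively zero) diameter")
    c(L = L, d = d)
  }
  inBounds <- function(y, x, m) y > m && y < H - m && x > m && x < W - m
  clash <- function(segs, parent, p0, p1, d) {
    if (!nrow(segs)) return(FALSE)
    for (i in seq_len(nrow(segs))) {
      s <- segs[i, ]
      if (s$id == parent) next                 # shares the junction node
      shared <- identical(c(s$y1, s$x1), c(p0[1], p0[2])) ||
                identical(c(s$y0, s$x0), c(p0[1], p0[2]))
      dd <- .segSegDist(p0, p1, c(s$y0, s$x0), c(s$y1, s$x1),
                        ta = if (shared) 0.35 else 0,
                        tb = if (shared) 0.35 else 0)
      if (dd < (d + s$d_px) / 2 + 2) return(TRUE)
    }
    FALSE
  }

  # Children leave each bifurcation at physiologic opening angles
  # (alternating signs, 18-32 degrees off the parent axis); branches are
  # clipped short near the canvas margin the way vessels shorten toward the
  # organ boundary, and a whole-tree restart is used when no collision-free
  # placement exists.
  conc0 <- spec@trunkConcentration
  grow <- function() {
    segs <- segs[0, ]
    ok <- FALSE
    for (att in 1:20) {
      g <- drawGeom(1L)
      y0 <- H / 2 + runif(1, -H / 24, H / 24); x0 <- 1
      a <- runif(1, -4, 4) * pi / 180
      y1 <- y0 + g["L"] * sin(a); x1 <- x0 + g["L"] * cos(a)
      if (inBounds(y1, x1, g["d"] / 2 + 2)) { ok <- TRUE; break }
    }
    if (!ok) return("phantom tree exceeds image bounds at level 1")
    segs[1, ] <- list(1L, 0L, 1L, y0, x0, round(y1), round(x1), a,
                      unname(g["d"]), unname(g["d"]) * pitch, conc0)
    nid <- 1L
    if (nl > 1L) for (gen in 2:nl) {
      parents <- segs[segs$gen == gen - 1L, ]
      k <- bf[gen - 1L]
      for (pi_ in seq_len(nrow(parents))) {
        p <- parents[pi_, ]
        for (j in seq_len(k)) {
          ok <- FALSE
          for (att in 1:20) {
            g <- drawGeom(gen)
            off <- if (k == 1) runif(1, -10, 10) else
              (if (j %% 2 == 1) 1 else -1) *
                (runif(1, 18, 32) + 12 * ((j - 1) %/% 2))
            a <- p$angle + off * pi / 180
            a <- max(-75, min(75, a * 180 / pi)) * pi / 180
            p0 <- c(p$y1, p$x1)
            m <- unname(g["d"]) / 2 + 2
            # clip the branch so it stays inside the margin box
            sy <- sin(a); cx <- cos(a)
            tmax <- min(
              if (sy > 0) (H - m - p0[1]) / sy else
                if (sy < 0) (1 + m - p0[1]) / sy else Inf,
              if (cx > 0) (W - m - p0[2]) / cx else
                if (cx < 0) (1 + m - p0[2]) / cx else Inf)
            L <- unname(g["L"])
            if (tmax < 0.4 * L) next
            L <- min(L, 0.97 * tmax)
            p1 <- c(p0[1] + L * sy, p0[2] + L * cx)
            if (!inBounds(p1[1], p1[2], m)) next
            if (clash(segs, p$id, p0, round(p1), g["d"])) next
            ok <- TRUE; break
          }
          if (!ok) return(paste0("phantom tree exceeds image bounds at ",
                                 "level ", gen,
                                 " (no collision-free placement found)"))
          nid <- nid + 1L
          segs[nid, ] <- list(nid, p$id, gen, p0[1], p0[2],
                              round(p1[1]), round(p1[2]), a,
                              unname(g["d"]), unname(g["d"]) * pitch,
                              conc0 *
                                spec@concentrationDecay^max(0, gen - 2))
        }
      }
    }
    segs
  }
  res <- NULL
  for (restart in 1:15) {
    res <- grow()
    if (is.data.frame(res)) break
  }
  if (!is.data.frame(res)) stop(res)
  res
}

# ground-truth level assignment: the farthest-leaf path-peeling rule applied
# directly to the generated tree (closed-form Chebyshev pixel-count lengths,
# no raster, no Dijkstra) -- an oracle independent of classifyLevels()
.truthLevels <- function(segs) {
  n <- nrow(segs)
  lev <- rep(NA_integer_, n)
  if (!n) return(lev)
  len <- pmax(abs(segs$y1 - segs$y0), abs(segs$x1 - segs$x0)) + 1
  kids <- split(segs$id, factor(segs$parent, levels = segs$id))
  far <- rep(NA_real_, n); farKid <- rep(NA_integer_, n)
  farLeaf <- rep(NA_integer_, n)
  # farthest cumulative length through each segment (iterate generations
  # bottom-up); distance ties resolved by the smaller terminal-leaf id,
  # mirroring the classifier's documented tie-break
  for (g in sort(unique(segs$gen), decreasing = TRUE)) {
    for (i in segs$id[segs$gen == g]) {
      ch <- kids[[as.character(i)]]
      if (is.null(ch) || !length(ch)) {
        far[i] <- len[i]; farKid[i] <- NA_integer_; farLeaf[i] <- i
      } else {
        best <- ch[order(-far[ch], farLeaf[ch])][1]
        far[i] <- len[i] + far[best]
        farKid[i] <- best
        farLeaf[i] <- farLeaf[best]
      }
    }
  }
  lev[1] <- 1L                            # inlet trunk is part of P1
  queue <- list()
  for (b in kids[["1"]]) queue[[length(queue) + 1L]] <- c(b, 1L)
  while (length(queue)) {
    it <- queue[[1]]; queue[[1]] <- NULL
    seg <- it[1]; L <- it[2]
    cur <- seg
    while (!is.na(cur)) {                 # claim the farthest-leaf path
      lev[cur] <- min(L, 5L)
      nxt <- farKid[cur]
      for (b in setdiff(kids[[as.character(cur)]], nxt))
        queue[[length(queue) + 1L]] <- c(b, L + 1L)
      cur <- nxt
    }
  }
  lev
}

#' Generate a synthetic vascular phantom
#'
#' Grows a random branching tree from an inlet stub at the left image
#' border, rasterises it into a binary vessel mask, renders the bright-field
#' channel by darkening tube interiors according to the attenuation model
#' A = epsilon*log10(c*d) + k relative to the background grayscale (the
#' darkest overlapping tube wins), and renders the fluorescent channel as an
#' intravascular plateau plus an extravascular halo decaying as
#' exp(-x/haloScale) with distance x from the vessel wall. Ground-truth
#' branch levels are computed by the farthest-leaf path-peeling rule on the
#' exact generated tree.
#'
#' The generator is fully deterministic for a fixed `spec@seed`.
#'
#' @param spec a [PhantomSpec-class].
#' @return a [PhantomBundle-class] with both channels, the truth mask, the
#'   truth graph (exact diameters, assigned levels) and per-edge
#'   concentrations (mg/mL, named by edge id).
#' @examples
#' b <- generatePhantom(PhantomSpec(imageHeight = 256, imageWidth = 256,
#'                                  nLevels = 3,
#'                                  lengthMeanUm = c(900, 600, 400),
#'                                  seed = 7))
#' b
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  set.seed(spec@seed)
  H <- spec@imageHeight; W <- spec@imageWidth
  segs <- .growTree(spec)
  lev <- .truthLevels(segs)

  maskM <- matrix(0L, H, W)
  bright <- matrix(spec@backgroundGray, H, W)
  if (nrow(segs)) {
    for (i in seq_len(nrow(segs))) {
      s <- segs[i, ]
      idx <- .tubePixels(H, W, s$y0, s$x0, s$y1, s$x1, s$d_px)
      if (!length(idx)) next
      maskM[idx] <- 1L
      cd <- s$conc * s$d_um
      val <- if (cd <= 0) spec@backgroundGray else
        spec@backgroundGray * 10^-(spec@epsilon * log10(cd) + spec@k)
      bright[idx] <- pmin(bright[idx], val)
    }
    # raster pockets pinched between diverging tubes at a junction are
    # not anatomy; left open they become skeleton rings downstream
    filled <- imageData(fillHull(Image(maskM)))
    storage.mode(filled) <- "integer"
    maskM <- filled
  }

  # fluorescent channel: plateau inside, exponential halo outside with
  # x = 0 exactly at the analytic vessel wall (distance to the tube
  # surface, not to rasterised pixel centers); the halo is evaluated out
  # to 6 decay lengths, beyond which it is under half a gray level
  fluor <- matrix(spec@fluorBackgroundGray, H, W)
  if (nrow(segs)) {
    cutPx <- 6 * spec@haloScaleUm / spec@pixelPitch
    distWall <- matrix(Inf, H, W)
    for (i in seq_len(nrow(segs))) {
      s <- segs[i, ]
      r <- s$d_px / 2
      rr <- max(1L, floor(min(s$y0, s$y1) - r - cutPx)):
            min(H, ceiling(max(s$y0, s$y1) + r + cutPx))
      cc <- max(1L, floor(min(s$x0, s$x1) - r - cutPx)):
            min(W, ceiling(max(s$x0, s$x1) + r + cutPx))
      yy <- rep(rr, times = length(cc))
      xx <- rep(cc, each = length(rr))
      vy <- s$y1 - s$y0; vx <- s$x1 - s$x0
      L2 <- vy * vy + vx * vx
      t <- if (L2 == 0) 0 else pmax(0, pmin(1, ((yy - s$y0) * vy +
                                                (xx - s$x0) * vx) / L2))
      dw <- sqrt((yy - s$y0 - t * vy)^2 + (xx - s$x0 - t * vx)^2) - r
      idx <- (xx - 1L) * H + yy
      distWall[idx] <- pmin(distWall[idx], dw)
    }
    halo <- ifelse(is.finite(distWall),
                   exp(-pmax(distWall, 0) * spec@pixelPitch /
                         spec@haloScaleUm), 0)
    fluor <- spec@fluorBackgroundGray + spec@fluorWallGray * halo
  }

  if (spec@noiseSdGray > 0) {
    bright <- bright + rnorm(length(bright), 0, spec@noiseSdGray)
    fluor <- fluor + rnorm(length(fluor), 0, spec@noiseSdGray)
  }
  bright <- pmin(pmax(bright, 0), 255)
  fluor <- pmin(pmax(fluor, 0), 255)

  # truth graph: node 1 = inlet origin; node (seg id + 1) = segment endpoint
  if (nrow(segs)) {
    hasKids <- segs$id %in% segs$parent
    nodes <- data.frame(
      id = c(1L, segs$id + 1L),
      y = c(round(segs$y0[1]), segs$y1),
      x = c(round(segs$x0[1]), segs$x1),
      kind = c("leaf", ifelse(hasKids, "bifurcation", "leaf")))
    if (nrow(segs) > 1) nodes$kind[2] <- "root"   # first main bifurcation
    edges <- data.frame(
      id = segs$id,
      from = ifelse(segs$parent == 0L, 1L, segs$parent + 1L),
      to = segs$id + 1L,
      length_px = 0, mean_diameter_px = segs$d_px,
      level = lev)
    paths <- vector("list", nrow(segs))
    for (i in seq_len(nrow(segs))) {
      nf <- nodes[nodes$id == edges$from[i], ]
      nt <- nodes[nodes$id == edges$to[i], ]
      paths[[i]] <- .bresenham(nf$y, nf$x, nt$y, nt$x)
      edges$length_px[i] <- nrow(paths[[i]])
    }
    graph <- VesselGraph(nodes, edges, paths, dim = c(H, W),
                         pixelPitch = spec@pixelPitch)
    tc <- setNames(segs$conc, segs$id)
  } else {
    graph <- VesselGraph(
      nodes = data.frame(id = integer(0), y = numeric(0), x = numeric(0),
                         kind = character(0)),
      edges = data.frame(id = integer(0), from = integer(0), to = integer(0),
                         length_px = numeric(0),
                         mean_diameter_px = numeric(0), level = integer(0)),
      paths = list(), dim = c(H, W), pixelPitch = spec@pixelPitch)
    tc <- numeric(0)
  }

  new("PhantomBundle",
      brightField = GrayImage(bright, "bright_field"),
      fluorescent = GrayImage(fluor, "fluorescent"),
      truthMask = VesselMask(maskM),
      truthGraph = graph,
      truthConcentration = tc,
      spec = spec)
}

#' Rasterise one tube onto a mask canvas
#'
#' Sets every pixel whose center lies within `diameterPx/2` of the segment
#' to foreground. The operation is idempotent and commutes with set union;
#' parts of the segment outside the canvas are clipped with a warning.
#'
#' @param p0,p1 numeric `c(y, x)` segment endpoints (1-based pixel
#'   coordinates).
#' @param diameterPx tube diameter in pixels (>= 1).
#' @param canvas a [VesselMask-class] to draw onto.
#' @return the updated [VesselMask-class].
#' @export
rasterizeTube <- function(p0, p1, diameterPx, canvas) {
  stopifnot(is(canvas, "VesselMask"))
  if (diameterPx < 1) stop("diameterPx must be >= 1")
  H <- nrow(canvas); W <- ncol(canvas)
  r <- diameterPx / 2
  if (min(p0[1], p1[1]) - r < 0.5 || max(p0[1], p1[1]) + r > H + 0.5 ||
      min(p0[2], p1[2]) - r < 0.5 || max(p0[2], p1[2]) + r > W + 0.5)
    warning("tube extends beyond the canvas; clipped")
  m <- canvas@.Data
  m[.tubePixels(H, W, p0[1], p0[2], p1[1], p1[2], diameterPx)] <- 1L
  VesselMask(m)
}
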