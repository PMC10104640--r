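## Vessel topology: skeleton -> graph conversion, root detection,
## five-level branch classification and per-level quantification.

#' @importFrom igraph graph_from_data_frame distances shortest_paths
#'   components E V delete_edges make_empty_graph add_edges as_ids
NULL

.borderDist <- function(y, x, dm) {
  if (any(is.na(dm))) return(rep(Inf, length(y)))
  pmin(y - 1, x - 1, dm[1] - y, dm[2] - x)
}

#' Vessel diameter at a skeleton pixel
#'
#' The Euclidean distance from the pixel to the nearest background pixel is
#' doubled (and reduced by one pixel so that ideal odd-width bands measure
#' exactly): diameter = 2*d_bg - 1.
#'
#' @param pixels `c(y, x)` or an n x 2 matrix of 1-based pixel coordinates.
#' @param mask the [VesselMask-class] the skeleton was extracted from.
#' @return numeric diameter(s) in pixels.
#' @export
pixelDiameter <- function(pixels, mask) {
  m <- .maskMat(mask)
  if (is.null(dim(pixels))) pixels <- matrix(pixels, ncol = 2)
  idx <- (pixels[, 2] - 1L) * nrow(m) + pixels[, 1]
  if (any(m[idx] != 1L)) stop("pixel lies outside the mask foreground")
  dt <- imageData(distmap(Image(m)))
  2 * dt[idx] - 1
}

# trace all edges of one 8-connected skeleton; internal workhorse
.traceGraph <- function(sk, mk, pixelPitch) {
  H <- nrow(sk); W <- ncol(sk)
  nb <- .nb8(sk)
  pix <- which(sk == 1L)
  py <- (pix - 1L) %% H + 1L
  px <- (pix - 1L) %/% H + 1L
  isNodePix <- (sk == 1L) & (nb == 1L | nb >= 3L | nb == 0L)

  # cluster adjacent branch (>=3 neighbour) pixels into single nodes
  nodeId <- matrix(0L, H, W)
  nodes <- list()
  nid <- 0L
  bifPix <- which((sk == 1L) & (nb >= 3L))
  if (length(bifPix)) {
    by_ <- (bifPix - 1L) %% H + 1L
    bx_ <- (bifPix - 1L) %/% H + 1L
    lab <- seq_along(bifPix)           # union-find over 8-adjacency
    posOf <- new.env()
    for (i in seq_along(bifPix)) assign(as.character(bifPix[i]), i,
                                        envir = posOf)
    find <- function(i) { while (lab[i] != i) i <- lab[i]; i }
    for (i in seq_along(bifPix)) {
      for (dy in -1:1) for (dx in -1:1) {
        if (dy == 0 && dx == 0) next
        y <- by_[i] + dy; x <- bx_[i] + dx
        if (y < 1 || x < 1 || y > H || x > W) next
        j0 <- mget(as.character((x - 1L) * H + y), envir = posOf,
                   ifnotfound = list(NULL))[[1]]
        if (!is.null(j0)) {
          ri <- find(i); rj <- find(j0)
          if (ri != rj) lab[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
    roots <- vapply(seq_along(bifPix), find, 0L)
    for (r in unique(roots)) {
      mem <- which(roots == r)
      cy <- mean(by_[mem]); cx <- mean(bx_[mem])
      d2 <- (by_[mem] - cy)^2 + (bx_[mem] - cx)^2
      best <- mem[order(d2, by_[mem], bx_[mem])][1]
      nid <- nid + 1L
      nodes[[nid]] <- list(id = nid, y = by_[best], x = bx_[best],
                           kind = "bifurcation")
      nodeId[bifPix[mem]] <- nid
    }
  }
  # leaves and isolated pixels
  endPix <- which((sk == 1L) & (nb == 1L | nb == 0L))
  for (p in endPix) {
    nid <- nid + 1L
    nodes[[nid]] <- list(id = nid, y = (p - 1L) %% H + 1L,
                         x = (p - 1L) %/% H + 1L, kind = "leaf")
    nodeId[p] <- nid
  }
  if (!nid) stop("cyclic skeleton component without endpoints or ",
                 "bifurcations is not supported")

  dt <- imageData(distmap(Image(mk)))
  visited <- matrix(FALSE, H, W)
  edges <- list(); paths <- list()
  seenDirect <- character(0)
  offs <- cbind(dy = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dx = c(-1, 0, 1, -1, 1, -1, 0, 1))
  nodePixList <- which(nodeId != 0L)
  addEdge <- function(from, to, pmat) {
    if (any(mk[(pmat[, 2] - 1L) * H + pmat[, 1]] == 0L))
      stop("skeleton pixel outside mask foreground")
    dvals <- 2 * dt[cbind(pmat[, 1], pmat[, 2])] - 1
    eid <- length(edges) + 1L
    edges[[eid]] <<- list(id = eid, from = from, to = to,
                          length_px = nrow(pmat),
                          mean_diameter_px = mean(dvals))
    paths[[eid]] <<- pmat
  }
  for (np in nodePixList) {
    ny <- (np - 1L) %% H + 1L; nx <- (np - 1L) %/% H + 1L
    for (o in seq_len(8)) {
      y <- ny + offs[o, 1]; x <- nx + offs[o, 2]
      if (y < 1 || x < 1 || y > H || x > W || sk[y, x] == 0L) next
      if (nodeId[y, x] != 0L) {
        # direct node-node adjacency
        if (nodeId[y, x] == nodeId[ny, nx]) next
        key <- paste(min(np, (x - 1L) * H + y), max(np, (x - 1L) * H + y))
        if (key %in% seenDirect) next
        seenDirect <- c(seenDirect, key)
        addEdge(nodeId[ny, nx], nodeId[y, x],
                rbind(c(ny, nx), c(y, x)))
        next
      }
      if (visited[y, x]) next
      pmat <- rbind(c(ny, nx), c(y, x))
      visited[y, x] <- TRUE
      prev <- c(ny, nx); cur <- c(y, x)
      repeat {
        nxt <- NULL
        for (o2 in seq_len(8)) {
          yy <- cur[1] + offs[o2, 1]; xx <- cur[2] + offs[o2, 2]
          if (yy < 1 || xx < 1 || yy > H || xx > W) next
          if (sk[yy, xx] == 0L) next
          if (yy == prev[1] && xx == prev[2]) next
          nxt <- c(yy, xx); break
        }
        if (is.null(nxt)) stop("skeleton trace dead-ended unexpectedly")
        pmat <- rbind(pmat, nxt)
        if (nodeId[nxt[1], nxt[2]] != 0L) {
          # a 1-2 pixel hop back into the starting cluster is a junction
          # adjacency artefact, not a genuine loop
          if (nodeId[nxt[1], nxt[2]] == nodeId[ny, nx] && nrow(pmat) <= 3)
            break
          addEdge(nodeId[ny, nx], nodeId[nxt[1], nxt[2]], pmat)
          break
        }
        visited[nxt[1], nxt[2]] <- TRUE
        prev <- cur; cur <- nxt
      }
    }
  }
  if (any(sk == 1L & !visited & nodeId == 0L))
    stop("cyclic skeleton structure (untraceable ring) is not supported")

  ndf <- do.call(rbind, lapply(nodes, function(n)
    data.frame(id = n$id, y = n$y, x = n$x, kind = n$kind)))
  if (length(edges)) {
    edf <- do.call(rbind, lapply(edges, function(e)
      data.frame(id = e$id, from = e$from, to = e$to,
                 length_px = e$length_px,
                 mean_diameter_px = e$mean_diameter_px)))
    edf$level <- NA_integer_
  } else {
    edf <- data.frame(id = integer(0), from = integer(0), to = integer(0),
                      length_px = numeric(0), mean_diameter_px = numeric(0),
                      level = integer(0))
  }
  VesselGraph(ndf, edf, paths, dim = c(H, W), pixelPitch = pixelPitch)
}

#' Build a vessel graph from a skeleton
#'
#' Skeleton pixels with one 8-neighbour become leaf nodes and pixels with
#' three or more become bifurcation pixels; adjacent bifurcation pixels are
#' merged into a single node located at the member pixel nearest the
#' cluster centroid. Edges are the degree-2 chains between nodes; each edge
#' records its ordered pixel path, its length as the path pixel count, and
#' its mean diameter from the distance transform of the mask
#' (2*d_bg - 1 per skeleton pixel).
#'
#' Disconnected skeletons yield per-component graphs; by default the
#' largest component is returned with a warning. With
#' `includeSatellites = TRUE` all components are merged into one graph
#' (satellites are later classified as level-5). Cyclic structures are
#' rejected with an error.
#'
#' @param skeleton a [SkeletonMatrix-class] (or 0/1 matrix).
#' @param mask the originating [VesselMask-class].
#' @param pixelPitch micrometres per pixel, recorded on the graph.
#' @param includeSatellites keep disconnected fragments (default FALSE).
#' @return a [VesselGraph-class].
#' @export
buildGraph <- function(skeleton, mask, pixelPitch = 10,
                       includeSatellites = FALSE) {
  sk <- if (is(skeleton, "SkeletonMatrix")) skeleton else
    SkeletonMatrix(skeleton)   # validity check rejects 2x2 blocks
  skm <- sk@.Data
  mk <- .maskMat(mask)
  if (!identical(dim(skm), dim(mk)))
    stop("skeleton and mask differ in shape")
  if (!sum(skm)) {
    return(VesselGraph(
      data.frame(id = integer(0), y = numeric(0), x = numeric(0),
                 kind = character(0)),
      data.frame(id = integer(0), from = integer(0), to = integer(0),
                 length_px = numeric(0), mean_diameter_px = numeric(0),
                 level = integer(0)),
      list(), dim = dim(skm), pixelPitch = pixelPitch))
  }
  # 8-connected components of the skeleton
  lab <- .label8(skm)
  sizes <- tabulate(lab[lab > 0])
  keep <- if (length(sizes) > 1 && !includeSatellites) {
    warning(length(sizes), " skeleton components; returning the largest")
    which.max(sizes)
  } else seq_along(sizes)
  g <- NULL
  for (comp in keep) {
    sub <- (lab == comp) * 1L
    gc_ <- .traceGraph(sub, mk, pixelPitch)
    g <- if (is.null(g)) gc_ else .mergeGraphs(g, gc_)
  }
  # a cycle within a component shows up as |E| >= |V|
  compN <- .graphComponents(g)
  for (cc in unique(compN$comp)) {
    vids <- compN$id[compN$comp == cc]
    ne <- sum(g@edges$from %in% vids | g@edges$to %in% vids)
    if (ne >= length(vids))
      stop("cyclic vascular structure detected (component with ",
           length(vids), " nodes and ", ne, " edges)")
  }
  g
}

# 8-connectivity labelling of a binary matrix via igraph components
.label8 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  pix <- which(m == 1L)
  lab <- matrix(0L, H, W)
  if (!length(pix)) return(lab)
  idx <- match(seq_len(H * W), pix)      # pixel -> vertex id
  elist <- NULL
  py <- (pix - 1L) %% H + 1L
  px <- (pix - 1L) %/% H + 1L
  for (o in list(c(1L, -1L), c(1L, 0L), c(1L, 1L), c(0L, 1L))) {
    y2 <- py + o[1]; x2 <- px + o[2]
    ok <- y2 >= 1 & y2 <= H & x2 >= 1 & x2 <= W
    p2 <- (x2 - 1L) * H + y2
    ok[ok] <- m[p2[ok]] == 1L
    if (any(ok))
      elist <- rbind(elist, cbind(idx[pix[ok]], idx[p2[ok]]))
  }
  gg <- igraph::make_empty_graph(n = length(pix), directed = FALSE)
  if (!is.null(elist))
    gg <- igraph::add_edges(gg, t(elist))
  cmp <- igraph::components(gg)$membership
  lab[pix] <- cmp
  lab
}

.mergeGraphs <- function(a, b) {
  offN <- max(0L, a@nodes$id)
  offE <- max(0L, a@edges$id)
  bn <- b@nodes; bn$id <- bn$id + offN
  be <- b@edges
  if (nrow(be)) {
    be$id <- be$id + offE
    be$from <- be$from + offN
    be$to <- be$to + offN
  }
  VesselGraph(rbind(a@nodes, bn), rbind(a@edges, be),
              c(a@paths, b@paths), dim = a@dim, pixelPitch = a@pixelPitch)
}

.graphComponents <- function(g) {
  if (!nrow(g@nodes)) return(data.frame(id = integer(0), comp = integer(0)))
  ig <- .asIgraph(g)
  data.frame(id = g@nodes$id,
             comp = igraph::components(ig)$membership[
               as.character(g@nodes$id)])
}

.asIgraph <- function(g) {
  vd <- data.frame(name = as.character(g@nodes$id))
  if (!nrow(g@edges))
    return(igraph::graph_from_data_frame(
      data.frame(from = character(0), to = character(0)),
      directed = FALSE, vertices = vd))
  ed <- data.frame(from = as.character(g@edges$from),
                   to = as.character(g@edges$to),
                   weight = g@edges$length_px,
                   eid = g@edges$id)
  igraph::graph_from_data_frame(ed, directed = FALSE, vertices = vd)
}

# the inlet is the root-incident edge whose far endpoint is a leaf at the
# image border: the injection vessel upstream of the first main
# bifurcation. Thinning erodes a tube's rounded end cap by about its
# radius, so "at the border" means within half the edge's diameter (plus
# `margin` pixels) of the nearest image edge.
.findInlet <- function(g, root, margin = 2) {
  ed <- g@edges; nd <- g@nodes
  inc <- ed[ed$from == root | ed$to == root, , drop = FALSE]
  if (!nrow(inc) || any(is.na(g@dim))) return(NA_integer_)
  far <- ifelse(inc$from == root, inc$to, inc$from)
  fk <- nd$kind[match(far, nd$id)]
  bd <- .borderDist(nd$y[match(far, nd$id)], nd$x[match(far, nd$id)], g@dim)
  cand <- which(fk == "leaf" &
                bd <= inc$mean_diameter_px / 2 + max(margin, 1))
  if (!length(cand)) return(NA_integer_)
  inc$id[cand[order(-inc$mean_diameter_px[cand])][1]]
}

#' Detect the root node of a vessel graph
#'
#' Node diameter is the maximum mean diameter of the node's incident edges.
#' The three bifurcation nodes with the largest diameters are candidate
#' roots; among them the node farthest from the image border (Chebyshev
#' distance to the nearest edge) is returned, with ties broken by larger
#' diameter and then row-major pixel order. A graph without bifurcations
#' degenerates to the largest-diameter leaf, returned with a warning.
#'
#' @param graph a [VesselGraph-class].
#' @return the root node id.
#' @export
detectRoot <- function(graph) {
  nd <- graph@nodes; ed <- graph@edges
  if (!nrow(nd)) stop("empty graph")
  ndia <- vapply(nd$id, function(v) {
    inc <- ed$mean_diameter_px[ed$from == v | ed$to == v]
    if (length(inc)) max(inc) else 0
  }, 0)
  bif <- which(nd$kind %in% c("bifurcation", "root"))
  if (!length(bif)) {
    warning("no bifurcation node; returning the largest-diameter leaf")
    return(nd$id[order(-ndia, nd$y, nd$x)][1])
  }
  ord <- bif[order(-ndia[bif], nd$y[bif], nd$x[bif])]
  top <- ord[seq_len(min(3L, length(ord)))]
  bd <- .borderDist(nd$y[top], nd$x[top], graph@dim)
  if (all(is.infinite(bd))) bd <- rep(0, length(top))  # no raster: diameter
  nd$id[top[order(-bd, -ndia[top], nd$y[top], nd$x[top])][1]]
}

#' Classify branches into hierarchical levels P1-P5
#'
#' Starting at the root, the `n` main branches (root-incident edges, minus
#' the inlet stub when one is identified) are processed: for each branch,
#' Dijkstra shortest-path distances (edge weights = pixel-count lengths)
#' identify the leaf reached through that branch farthest from the root;
#' the root-to-leaf path is claimed at the current level. Bifurcation nodes
#' on a claimed path then seed the next level from their remaining
#' branches, and so on. Iteration continues until every edge is claimed;
#' all levels beyond 5 are recorded as level 5, so deeper generations
#' accumulate in P5. Ties in the farthest-leaf choice are broken by the
#' smaller leaf node id.
#'
#' @param graph a [VesselGraph-class].
#' @param root root node id; defaults to [detectRoot()].
#' @param inletMargin border margin (px) for inlet-stub identification.
#' @return the graph with `level` filled in on every edge and the root
#'   node's kind set to `"root"`.
#' @export
classifyLevels <- function(graph, root = NULL, inletMargin = 2) {
  g <- graph
  if (!nrow(g@edges)) return(g)
  if (is.null(root)) root <- detectRoot(g)
  if (!root %in% g@nodes$id) stop("root is not a node of the graph")
  ig <- .asIgraph(g)
  nE <- nrow(g@edges)
  lev <- rep(NA_integer_, nE)
  queued <- rep(FALSE, nE)

  # reachability from the root (satellites are allowed only when they will
  # be swept into level 5 at the end)
  droot <- igraph::distances(ig, v = as.character(root))
  mainComp <- colnames(droot)[is.finite(droot[1, ])]
  leaves <- g@nodes$id[g@nodes$kind == "leaf"]
  unreachable <- setdiff(as.character(leaves), mainComp)
  satellites <- !as.character(g@edges$from) %in% mainComp

  inlet <- .findInlet(g, root, inletMargin)
  if (!is.na(inlet)) {
    lev[inlet] <- 1L
    queued[inlet] <- TRUE
  }
  incRoot <- g@edges$id[g@edges$from == root | g@edges$to == root]
  mains <- setdiff(incRoot, if (is.na(inlet)) integer(0) else inlet)
  queue <- lapply(sort(mains), function(e) c(root, e, 1L))
  queued[mains] <- TRUE

  eFrom <- g@edges$from; eTo <- g@edges$to
  while (length(queue)) {
    it <- queue[[1]]; queue[[1]] <- NULL
    v <- it[1]; e <- it[2]; L <- it[3]
    claimed <- which(!is.na(lev))
    dropE <- union(claimed,
                   setdiff(g@edges$id[eFrom == v | eTo == v], e))
    sub <- igraph::delete_edges(ig, which(g@edges$id %in% dropE))
    dd <- igraph::distances(sub, v = as.character(v),
                            to = as.character(leaves))
    reach <- leaves[is.finite(dd[1, ]) & leaves != v]
    if (!length(reach)) { lev[e] <- min(L, 5L); next }
    dr <- dd[1, match(as.character(reach), colnames(dd))]
    target <- reach[order(-dr, reach)][1]
    sp <- igraph::shortest_paths(sub, from = as.character(v),
                                 to = as.character(target),
                                 output = "both")
    pe <- igraph::E(sub)$eid[as.integer(sp$epath[[1]])]
    pv <- as.integer(igraph::as_ids(sp$vpath[[1]]))
    lev[pe] <- min(L, 5L)
    for (u in pv) {
      ue <- g@edges$id[(eFrom == u | eTo == u)]
      for (f in ue) {
        if (queued[f] || !is.na(lev[f])) next
        queued[f] <- TRUE
        queue[[length(queue) + 1L]] <- c(u, f, L + 1L)
      }
    }
  }
  if (length(unreachable)) {
    if (!any(satellites))
      stop("leaf node(s) ", paste(unreachable, collapse = ", "),
           " unreachable from the root")
    lev[is.na(lev)] <- 5L      # disconnected satellites sweep into P5
  }
  if (anyNA(lev)) lev[is.na(lev)] <- 5L
  g@edges$level <- as.integer(lev)
  g@nodes$kind[g@nodes$id == root] <- "root"
  g
}

#' Per-level branch summaries over a time series
#'
#' For each time point and level P1-P5: branch count, accumulated length
#' (pixels and micrometres, the sum of member edge pixel counts), mean
#' diameter, and count/length ratios normalised to the first time point.
#' A level absent at a time point contributes count 0 and ratio 0.
#'
#' @param graphs list of level-classified [VesselGraph-class] objects
#'   sharing a reference (first) time point.
#' @param times optional numeric time labels (default 0, 1, ...).
#' @return a tidy data.frame.
#' @export
summarizeLevels <- function(graphs, times = NULL) {
  if (!length(graphs)) stop("empty graph sequence")
  if (is.null(times)) times <- seq_along(graphs) - 1
  rows <- list()
  for (t in seq_along(graphs)) {
    g <- graphs[[t]]
    ed <- g@edges
    if (nrow(ed) && anyNA(ed$level))
      stop("graph at time point ", t, " has unassigned levels")
    for (l in 1:5) {
      sel <- ed[!is.na(ed$level) & ed$level == l, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        time = times[t], level = l, n_branches = nrow(sel),
        length_px = sum(sel$length_px),
        length_um = sum(sel$length_px) * g@pixelPitch,
        mean_diameter_px = if (nrow(sel))
          mean(sel$mean_diameter_px) else NA_real_,
        mean_diameter_um = if (nrow(sel))
          mean(sel$mean_diameter_px) * g@pixelPitch else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  ref <- out[out$time == times[1], ]
  rr <- function(v, v0) ifelse(v0 > 0, v / v0, ifelse(v == 0, 0, NA))
  out$count_ratio <- rr(out$n_branches,
                        ref$n_branches[match(out$level, ref$level)])
  out$length_ratio <- rr(out$length_px,
                         ref$length_px[match(out$level, ref$level)])
  out
}
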