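# Shared fixtures: scaled-down phantom specs, hand-built graphs, random
# blob masks, and a brute-force shortest-path oracle.

# small, fast phantom for unit tests (full-size defaults are exercised in
# the acceptance suite)
smallSpec <- function(seed = 1L, ...) {
  args <- list(imageHeight = 320L, imageWidth = 320L, nLevels = 3L,
               diameterMeanUm = c(300, 140, 60),
               diameterSdUm = c(15, 8, 5),
               lengthMeanUm = c(1500, 800, 500),
               seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(PhantomSpec, args)
}

# random union-of-discs binary mask
blobMask <- function(n = 6, size = 80L) {
  m <- matrix(0L, size, size)
  for (k in seq_len(n)) {
    cy <- sample(10:(size - 10), 1)
    cx <- sample(10:(size - 10), 1)
    r <- sample(3:12, 1)
    rr <- pmax(1, cy - r):pmin(size, cy + r)
    cc <- pmax(1, cx - r):pmin(size, cx + r)
    yy <- rep(rr, times = length(cc))
    xx <- rep(cc, each = length(rr))
    sel <- (yy - cy)^2 + (xx - cx)^2 <= r^2
    m[(xx[sel] - 1L) * size + yy[sel]] <- 1L
  }
  m
}

comp8 <- function(m) {
  if (!sum(m)) return(0L)
  as.integer(max(vasq:::.label8(m)))
}

# abstract VesselGraph from a node table and an edge list with lengths
# and diameters; pixel paths are straight segments between node coords
makeGraph <- function(nodes, edges, dim = c(NA_integer_, NA_integer_)) {
  paths <- lapply(seq_len(nrow(edges)), function(i) {
    a <- nodes[nodes$id == edges$from[i], ]
    b <- nodes[nodes$id == edges$to[i], ]
    vasq:::.bresenham(a$y, a$x, b$y, b$x)
  })
  edges$level <- if ("level" %in% names(edges)) edges$level else NA_integer_
  VesselGraph(nodes, edges, paths, dim = dim)
}

# brute-force shortest path by exhaustive simple-path enumeration
bruteShortest <- function(edges, from, to) {
  best <- Inf
  rec <- function(v, seen, acc) {
    if (v == to) { best <<- min(best, acc); return(invisible()) }
    for (i in seq_len(nrow(edges))) {
      u <- if (edges$from[i] == v) edges$to[i]
           else if (edges$to[i] == v) edges$from[i] else next
      if (u %in% seen) next
      if (acc + edges$w[i] >= best) next
      rec(u, c(seen, u), acc + edges$w[i])
    }
  }
  rec(from, from, 0)
  best
}

# 16 training + 4 held-out 128x128 patches sampled from full phantoms
phantomPatches <- function(seeds, perPhantom = 4L) {
  imgs <- list(); msks <- list()
  for (s in seeds) {
    b <- generatePhantom(PhantomSpec(seed = s))
    im <- b@brightField@.Data
    mk <- b@truthMask@.Data
    offs <- list()
    for (oy in seq(1, 897, 128)) for (ox in seq(1, 897, 128)) {
      f <- mean(mk[oy:(oy + 127), ox:(ox + 127)])
      if (f > 0.03 && f < 0.9) offs[[length(offs) + 1L]] <- c(oy, ox, f)
    }
    offs <- offs[order(-vapply(offs, `[`, 0, 3))]
    offs <- offs[seq_len(min(perPhantom, length(offs)))]
    for (o in offs) {
      imgs[[length(imgs) + 1L]] <- im[o[1]:(o[1] + 127), o[2]:(o[2] + 127)]
      msks[[length(msks) + 1L]] <- mk[o[1]:(o[1] + 127), o[2]:(o[2] + 127)]
    }
  }
  list(images = imgs, masks = msks)
}
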