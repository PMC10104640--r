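## Skeleton extraction: iterative thinning with two alternating directional
## subiterations, in the spirit of the classic two-pass (Zhang-Suen style)
## rule set -- one pass removes redundant pixels on the north-west corner /
## south-east boundary, the other on the south-east corner / north-west
## boundary -- until only a connected, single-pixel-wide centerline remains.

#' Reduce a binary mask to a single-pixel-wide skeleton
#'
#' Pixels are deleted by the two alternating directional subiterations until
#' no pixel can be removed. Within each subiteration candidates are
#' collected in parallel and then deleted sequentially with their deletion
#' conditions re-checked on the updating raster, which preserves the
#' 8-connected component structure (endpoints are never removed). A final
#' cleanup removes any residual fully-set 2x2 block by deleting a simple,
#' non-endpoint member. The operation is idempotent.
#'
#' @param mask a [VesselMask-class] or 0/1 matrix.
#' @return a [SkeletonMatrix-class]; empty input gives an empty skeleton.
#' @export
skeletonize <- function(mask) {
  m <- .maskMat(mask)
  SkeletonMatrix(cpp_thin(m))
}

# 8-neighbour count for every pixel of a binary matrix
.nb8 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(0L, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  pad[1:H, 1:W] + pad[1:H, 2:(W + 1)] + pad[1:H, 3:(W + 2)] +
    pad[2:(H + 1), 1:W] + pad[2:(H + 1), 3:(W + 2)] +
    pad[3:(H + 2), 1:W] + pad[3:(H + 2), 2:(W + 1)] + pad[3:(H + 2), 3:(W + 2)]
}

#' Prune short terminal spurs from a skeleton
#'
#' Removes, in one pass, every terminal chain shorter than `minLen` pixels
#' that ends at a junction; true branches and isolated paths are kept.
#' Thinning artefacts at junctions typically produce such spurs.
#'
#' @param skeleton a [SkeletonMatrix-class].
#' @param minLen spur length threshold in pixels (default 5).
#' @return a pruned [SkeletonMatrix-class].
#' @export
pruneSpurs <- function(skeleton, minLen = 5L) {
  m <- .maskMat(skeleton)
  nb <- .nb8(m)
  ends <- which(m == 1L & nb == 1L, arr.ind = TRUE)
  H <- nrow(m)
  offs <- expand.grid(dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0), ]
  for (e in seq_len(nrow(ends))) {
    chain <- list(ends[e, ])
    prev <- c(-1L, -1L)
    cur <- ends[e, ]
    repeat {
      nbs <- list()
      for (o in seq_len(nrow(offs))) {
        y <- cur[1] + offs$dy[o]; x <- cur[2] + offs$dx[o]
        if (y < 1 || x < 1 || y > H || x > ncol(m)) next
        if (m[y, x] == 1L && !(y == prev[1] && x == prev[2]))
          nbs[[length(nbs) + 1L]] <- c(y, x)
      }
      if (length(nbs) != 1L) break   # junction (or dead end) reached
      nxt <- nbs[[1]]
      if (nb[nxt[1], nxt[2]] >= 3L) {
        # chain terminates at a junction pixel: a spur candidate
        if (length(chain) < minLen)
          for (p in chain) m[p[1], p[2]] <- 0L
        break
      }
      prev <- cur; cur <- nxt
      chain[[length(chain) + 1L]] <- cur
      if (length(chain) >= minLen) break
    }
  }
  # cutting a spur can leave a redundant bump at the junction; re-thinning
  # is idempotent elsewhere and absorbs it
  SkeletonMatrix(cpp_thin(m))
}
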