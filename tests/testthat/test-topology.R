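test_that("a straight path yields two leaves and one edge of full length", {
  m <- matrix(0L, 11, 40)
  m[6, 5:34] <- 1L    # 30 px path
  g <- buildGraph(SkeletonMatrix(m), VesselMask(m))
  nd <- graphNodes(g); ed <- graphEdges(g)
  expect_identical(sort(nd$kind), c("leaf", "leaf"))
  expect_identical(nrow(ed), 1L)
  expect_equal(ed$length_px, 30)
})

test_that("a symmetric Y yields one bifurcation, three leaves, three edges", {
  m <- matrix(0L, 41, 41)
  m[21, 2:21] <- 1L                       # trunk, 20 px
  for (i in 1:15) { m[21 - i, 21 + i] <- 1L; m[21 + i, 21 + i] <- 1L }
  g <- buildGraph(SkeletonMatrix(m), VesselMask(m))
  nd <- graphNodes(g)
  expect_identical(sum(nd$kind == "bifurcation"), 1L)
  expect_identical(sum(nd$kind == "leaf"), 3L)
  expect_identical(nrow(graphEdges(g)), 3L)
})

test_that("a plus-sign collapses to one 4-way bifurcation with 4 edges", {
  m <- matrix(0L, 21, 21)
  m[11, 2:20] <- 1L
  m[2:20, 11] <- 1L
  g <- buildGraph(SkeletonMatrix(m), VesselMask(m))
  nd <- graphNodes(g)
  expect_identical(sum(nd$kind == "bifurcation"), 1L)
  expect_identical(nrow(graphEdges(g)), 4L)
  b <- nd[nd$kind == "bifurcation", ]
  expect_identical(c(b$y, b$x), c(11L, 11L))
})

test_that("pixel diameters follow the 2*d - 1 rule on ideal bands", {
  for (w in c(3, 5)) {
    m <- matrix(0L, 20, 30)
    lo <- 10 - (w - 1) / 2
    m[lo:(lo + w - 1), 5:25] <- 1L
    expect_equal(pixelDiameter(c(10, 15), VesselMask(m)), w)
  }
  single <- matrix(0L, 9, 9); single[5, 5] <- 1L
  expect_equal(pixelDiameter(c(5, 5), VesselMask(single)), 1)
  expect_error(pixelDiameter(c(1, 1), VesselMask(single)), "outside")
})

test_that("2x2 blocks and cyclic skeletons are rejected", {
  m <- matrix(0L, 10, 10); m[4:5, 4:5] <- 1L
  expect_error(buildGraph(m, VesselMask(m)), "2x2")
  ring <- matrix(0L, 12, 12)
  ring[4, 4:8] <- 1L; ring[8, 4:8] <- 1L; ring[5:7, 4] <- 1L
  ring[5:7, 8] <- 1L
  expect_error(buildGraph(SkeletonMatrix(ring), VesselMask(ring)),
               "cyclic|ring")
})

test_that("disconnected skeletons return the largest component", {
  m <- matrix(0L, 21, 41)
  m[5, 2:35] <- 1L
  m[15, 2:6] <- 1L
  expect_warning(g <- buildGraph(SkeletonMatrix(m), VesselMask(m)),
                 "largest")
  expect_identical(nrow(graphEdges(g)), 1L)
  expect_equal(graphEdges(g)$length_px, 34)
})

test_that("root detection prefers thick interior bifurcations", {
  nodes <- data.frame(id = 1:6,
                      y = c(2, 30, 30, 50, 10, 58),
                      x = c(2, 30, 45, 45, 45, 50),
                      kind = c("leaf", "bifurcation", "bifurcation",
                               "leaf", "leaf", "leaf"))
  edges <- data.frame(id = 1:5,
                      from = c(1, 2, 2, 3, 3),
                      to = c(2, 3, 5, 4, 6),
                      length_px = c(40, 20, 25, 22, 15),
                      mean_diameter_px = c(9, 5, 4, 3, 3))
  g <- makeGraph(nodes, edges, dim = c(60L, 60L))
  # node 2 carries the thickest edge and sits interior -> root
  expect_identical(detectRoot(g), 2L)

  # equal-diameter candidates: the border-adjacent one loses
  edges2 <- edges
  edges2$mean_diameter_px <- c(9, 9, 4, 3, 3)
  nodes2 <- nodes
  nodes2$y[2] <- 59   # push node 2 against the border
  g2 <- makeGraph(nodes2, edges2, dim = c(60L, 60L))
  expect_identical(detectRoot(g2), 3L)

  # no bifurcation at all: largest-diameter leaf with a warning
  chain <- makeGraph(
    data.frame(id = 1:2, y = c(5, 5), x = c(5, 25),
               kind = c("leaf", "leaf")),
    data.frame(id = 1, from = 1, to = 2, length_px = 21,
               mean_diameter_px = 4),
    dim = c(30L, 30L))
  expect_warning(r <- detectRoot(chain), "bifurcation")
  expect_true(r %in% 1:2)
})

test_that("level classification follows farthest-leaf path peeling", {
  # root with a single chain -> everything is P1
  chain <- makeGraph(
    data.frame(id = 1:3, y = c(10, 10, 10), x = c(5, 20, 35),
               kind = c("leaf", "bifurcation", "leaf")),
    data.frame(id = 1:2, from = c(1, 2), to = c(2, 3),
               length_px = c(16, 16), mean_diameter_px = c(4, 4)),
    dim = c(20L, 40L))
  out <- classifyLevels(chain, root = 2)
  expect_true(all(graphEdges(out)$level == 1L))

  # trunk splits into long arm A and short arm B; B splits again:
  # both main branches carry a P1 path, B's remaining sub-branch is P2
  nodes <- data.frame(id = 1:5,
                      y = c(30, 30, 10, 36, 44),
                      x = c(10, 20, 55, 30, 36),
                      kind = c("leaf", "bifurcation", "leaf",
                               "bifurcation", "leaf"))
  # node 5 via node 4 is farther (10 + 20) than ... add second leaf on 4
  nodes <- rbind(nodes, data.frame(id = 6, y = 50, x = 28, kind = "leaf"))
  edges <- data.frame(id = 1:5,
                      from = c(1, 2, 2, 4, 4),
                      to = c(2, 3, 4, 5, 6),
                      length_px = c(11, 40, 10, 20, 5),
                      mean_diameter_px = c(8, 4, 5, 3, 3))
  g <- makeGraph(nodes, edges, dim = c(60L, 60L))
  out <- classifyLevels(g, root = 2)
  lv <- graphEdges(out)$level
  # inlet (edge 1) P1; arm A (edge 2) P1; B chain via longest leaf
  # (edges 3 + 4) P1; B's short sub-branch (edge 5) P2
  expect_identical(lv, c(1L, 1L, 1L, 1L, 2L))

  # brute-force distance agreement on this graph
  for (lf in c(3, 5, 6)) {
    ig <- vasq:::.asIgraph(g)
    dd <- igraph::distances(ig, v = "2", to = as.character(lf))
    ew <- data.frame(from = edges$from, to = edges$to, w = edges$length_px)
    expect_equal(as.numeric(dd), bruteShortest(ew, 2, lf))
  }
})

test_that("a depth-7 binary tree caps at level 5", {
  # abstract complete binary tree, depth 7 below the root
  nodes <- data.frame(id = 1L, y = 1, x = 1, kind = "root")
  edges <- data.frame(id = integer(0), from = integer(0), to = integer(0),
                      length_px = numeric(0), mean_diameter_px = numeric(0))
  nid <- 1L; frontier <- 1L
  for (d in 1:7) {
    nf <- c()
    for (v in frontier) for (j in 1:2) {
      nid <- nid + 1L
      nodes <- rbind(nodes, data.frame(id = nid, y = d * 3, x = nid,
                                       kind = if (d == 7) "leaf" else
                                         "bifurcation"))
      edges <- rbind(edges, data.frame(id = nid - 1L, from = v, to = nid,
                                       length_px = 10 + nid %% 3,
                                       mean_diameter_px = 8 - d))
      nf <- c(nf, nid)
    }
    frontier <- nf
  }
  paths <- lapply(seq_len(nrow(edges)), function(i)
    cbind(c(1L, 2L), c(1L, 2L)))
  edges$level <- NA_integer_
  g <- VesselGraph(nodes, edges, paths)
  out <- classifyLevels(g, root = 1)
  lv <- graphEdges(out)$level
  expect_false(anyNA(lv))
  expect_identical(max(lv), 5L)
  expect_identical(min(lv), 1L)
  expect_identical(length(lv), 254L)
})

test_that("level assignment is invariant under 90-degree rotations", {
  b <- generatePhantom(smallSpec(seed = 6, noiseSdGray = 0))
  mk <- b@truthMask@.Data
  sk <- pruneSpurs(skeletonize(VesselMask(mk)))
  g0 <- classifyLevels(buildGraph(sk, VesselMask(mk)))
  lv0 <- sort(table(graphEdges(g0)$level))
  mk90 <- t(mk)[ncol(mk):1, ]
  sk90 <- pruneSpurs(skeletonize(VesselMask(mk90)))
  g90 <- classifyLevels(buildGraph(sk90, VesselMask(mk90)))
  lv90 <- sort(table(graphEdges(g90)$level))
  expect_identical(lv0, lv90)
})

test_that("level summaries normalise against the first time point", {
  mkg <- function(lv, len) makeGraph(
    data.frame(id = 1:(length(lv) + 1), y = seq_along(c(0, lv)) * 2,
               x = 3, kind = c("root", rep("leaf", length(lv)))),
    data.frame(id = seq_along(lv), from = 1, to = seq_along(lv) + 1,
               length_px = len, mean_diameter_px = 4, level = lv),
    dim = c(99L, 9L))
  g0 <- mkg(c(1L, 3L, 3L), c(10, 8, 8))
  g1 <- mkg(c(1L, 3L), c(10, 8))       # half the P3 length vanishes
  out <- summarizeLevels(list(g0, g1))
  expect_identical(nrow(out), 10L)
  t0 <- out[out$time == 0, ]
  expect_true(all(t0$count_ratio[t0$n_branches > 0] == 1))
  p3 <- out[out$time == 1 & out$level == 3, ]
  expect_equal(p3$length_ratio, 0.5)
  p2 <- out[out$time == 1 & out$level == 2, ]
  expect_identical(p2$n_branches, 0L)
  expect_equal(p2$count_ratio, 0)
  expect_error(summarizeLevels(list()), "empty")
})
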