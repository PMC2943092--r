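# Skeleton-to-graph conversion, pruning, attribute normalization, I/O

test_that("a plus-sign skeleton yields one 4-way bifurcation and four endpoints", {
  fp <- detectFeaturePoints(plusSkeleton())
  expect_equal(sum(fp$kind == "bifurcation"), 1)
  expect_equal(sum(fp$kind == "endpoint"), 4)
  te <- traceEdges(plusSkeleton())
  expect_equal(nrow(te$edges), 4)
  expect_equal(sort(te$nodes$degree), c(1, 1, 1, 1, 4))
})

test_that("a straight line yields two endpoints and one edge with exact distances", {
  sk <- lineSkeleton(len = 10)
  fp <- detectFeaturePoints(sk)
  expect_equal(nrow(fp), 2)
  expect_true(all(fp$kind == "endpoint"))
  te <- traceEdges(sk)
  expect_equal(nrow(te$edges), 1)
  expect_equal(te$edges$dvp, 9)
  expect_equal(te$edges$de, 9)
})

test_that("an L-shaped path accumulates unit and diagonal steps correctly", {
  # 5 px per arm meeting at a corner: dvp 8, de 4*sqrt(2)
  pts <- rbind(cbind(10, 5:9), cbind(9:6, 9))
  sk <- maskFromPoints(pts, 20, 20)
  te <- traceEdges(sk)
  expect_equal(nrow(te$edges), 1)
  expect_equal(te$edges$dvp, 8)
  expect_equal(te$edges$de, 4 * sqrt(2))
})

test_that("a Y-shaped skeleton localizes its junction to within a pixel", {
  pts <- rbind(cbind(20:11, 15),                       # stem going up
               cbind(10 - 1:8, 15 + 1:8),              # arm up-right
               cbind(10 - 1:8, 15 - 1:8))              # arm up-left
  sk <- maskFromPoints(rbind(pts, cbind(10, 15)), 30, 30)
  fp <- detectFeaturePoints(sk)
  bif <- fp[fp$kind == "bifurcation", ]
  expect_equal(nrow(bif), 1)
  expect_lte(max(abs(c(bif$row, bif$col) - c(10, 15))), 1)
  expect_equal(sum(fp$kind == "endpoint"), 3)
})

test_that("attribute normalization divides by the mean and errors on empty graphs", {
  nodes <- data.frame(id = 1:4, row = c(0, 0, 0, 0), col = c(0, 10, 30, 60))
  edges <- data.frame(from = 1:3, to = 2:4,
                      dvp = c(10, 20, 30), de = c(10, 20, 30))
  g <- graphFromTables(nodes, edges)
  expect_equal(edges(g)$a1, c(0.5, 1.0, 1.5))
  expect_equal(mean(edges(g)$a1), 1, tolerance = 1e-12)
  expect_equal(mean(edges(g)$a2), 1, tolerance = 1e-12)

  empty <- new("VascularGraph",
               nodes = nodes[, ],
               edges = edges[0, ],
               sourceShape = c(100L, 100L))
  expect_error(normalizeAttributes(empty), class = "fundusregEmptyGraph")
})

test_that("normalized attributes are invariant to uniform scaling", {
  set.seed(11)
  g <- randomGraph(8)
  t <- SimilarityTransform(scale = 2.7, rotation = 0.4,
                           translation = c(5, -3))
  gs <- transformGraph(g, t)
  expect_equal(edges(gs)$a1, edges(g)$a1, tolerance = 1e-12)
  expect_equal(edges(gs)$a2, edges(g)$a2, tolerance = 1e-12)
})

test_that("degree sum equals twice the edge count", {
  set.seed(12)
  for (n in c(5, 9, 14)) {
    g <- randomGraph(n, extraEdges = 2)
    expect_equal(sum(nodes(g)$degree), 2 * nrow(edges(g)))
  }
})

test_that("pruning removes a short spur and dissolves the leftover degree-2 node", {
  # path 1-2-3 with a 3-px spur at node 2
  nodes <- data.frame(id = 1:4,
                      row = c(0, 0, 0, 3), col = c(0, 20, 45, 20))
  edges <- data.frame(from = c(1, 2, 2), to = c(2, 3, 4),
                      dvp = c(20, 25, 3), de = c(20, 25, 3))
  g <- graphFromTables(nodes, edges)
  p <- pruneGraph(g, minEdgePx = 5)
  expect_equal(nrow(edges(p)), 1)
  expect_setequal(nodes(p)$id, c(1, 3))
  expect_equal(edges(p)$dvp, 45)          # concatenated path distances
  expect_equal(edges(p)$de, 45)

  # minEdgePx = 0 leaves the graph unchanged (modulo normalization)
  p0 <- pruneGraph(g, minEdgePx = 0)
  expect_equal(nrow(edges(p0)), 3)
})

test_that("pruning clears injected spurs but keeps every true edge", {
  set.seed(13)
  g <- randomGraph(10)
  n <- nodes(g); e <- edges(g)
  # inject 10 spurs of <= 4 px (not at degree-2 nodes: removing a spur
  # there correctly dissolves the host and concatenates its edges)
  nid <- max(n$id)
  hostPool <- n$id[n$degree != 2]
  for (k in 1:10) {
    host <- sample(hostPool, 1)
    nid <- nid + 1L
    hp <- n[match(host, n$id), ]
    n <- rbind(n, data.frame(id = nid, row = hp$row + 2, col = hp$col + 2,
                             degree = 1L, kind = "endpoint"))
    e2 <- data.frame(from = host, to = nid, dvp = runif(1, 2, 4),
                     de = 2)
    e2$path <- list(NULL)
    e2$a1 <- NA_real_; e2$a2 <- NA_real_
    e <- rbind(e, e2[, names(e)])
  }
  gi <- fundusreg:::makeVascularGraph(n, e, g@sourceShape)
  p <- pruneGraph(gi, minEdgePx = 10)
  key <- function(ee) paste(pmin(ee$from, ee$to), pmax(ee$from, ee$to))
  expect_true(all(key(edges(g)) %in% key(edges(p))))
  expect_false(any(nodes(p)$id > max(nodes(g)$id)))
})

test_that("component filtering drops short isolated squiggles", {
  set.seed(14)
  g <- randomGraph(8)
  n <- nodes(g); e <- edges(g)
  n <- rbind(n, data.frame(id = c(100, 101), row = c(150, 160),
                           col = c(150, 160), degree = 1L,
                           kind = "endpoint"))
  e2 <- data.frame(from = 100, to = 101, dvp = 30, de = 14.14)
  e2$path <- list(NULL); e2$a1 <- NA_real_; e2$a2 <- NA_real_
  e <- rbind(e, e2[, names(e)])
  gi <- fundusreg:::makeVascularGraph(n, e, g@sourceShape)
  f <- filterComponents(gi, minComponentPx = 100)
  expect_false(any(nodes(f)$id %in% c(100, 101)))
  expect_equal(nrow(edges(f)), nrow(edges(g)))
})

test_that("graph construction from clean skeletons recovers every junction precisely", {
  for (sd in 711:713) {
    spec <- phantomSpec(seed = sd, imageShape = c(420L, 500L),
                        rootLength = 130, treeDepth = 3L, nTrees = 1L,
                        noiseSd = 0, illuminationAmp = 0)
    tree <- generateTree(spec)
    m <- matrix(FALSE, 420, 500)
    for (p in tree$segments$path) {
      st <- pmax(1L, ceiling(sqrt(rowSums(diff(p)^2)) / 0.4))
      rr <- unlist(mapply(function(a, b, k) seq(a, b, length.out = k + 1),
                          p[-nrow(p), 1], p[-1, 1], st))
      cc <- unlist(mapply(function(a, b, k) seq(a, b, length.out = k + 1),
                          p[-nrow(p), 2], p[-1, 2], st))
      ri <- round(rr) + 1; ci <- round(cc) + 1
      ok <- ri >= 1 & ri <= 420 & ci >= 1 & ci <= 500
      m[cbind(ri[ok], ci[ok])] <- TRUE
    }
    g <- buildVascularGraph(thinMask(m), minEdgePx = 5, minComponentPx = 0)
    gt <- treeGraph(tree, spec$imageShape)
    gtb <- as.matrix(nodes(gt)[nodes(gt)$kind == "bifurcation",
                               c("row", "col")])
    exn <- as.matrix(nodes(g)[, c("row", "col")])
    d <- sqrt(outer(gtb[, 1], exn[, 1], "-")^2 +
                outer(gtb[, 2], exn[, 2], "-")^2)
    nn <- apply(d, 1, min)
    expect_gte(mean(nn <= 2), 0.9)
    expect_lte(median(nn), 2)
  }
})

test_that("graphs round-trip through JSON", {
  set.seed(15)
  g <- randomGraph(7)
  f <- tempfile(fileext = ".json")
  writeVascularGraph(g, f)
  back <- readVascularGraph(f)
  expect_equal(nodes(back)$id, nodes(g)$id)
  expect_equal(nodes(back)$row, nodes(g)$row)
  expect_equal(edges(back)$dvp, edges(g)$dvp)
  expect_equal(edges(back)$a1, edges(g)$a1)
  unlink(f)
})
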