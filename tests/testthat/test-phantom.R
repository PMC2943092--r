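# Synthetic phantom generator: trees, rendering, pairs, ground truth

test_that("tree generation is reproducible and respects depth combinatorics", {
  spec <- testSpec(701)
  t1 <- generateTree(spec)
  t2 <- generateTree(spec)
  expect_identical(t1$segments$path, t2$segments$path)
  expect_identical(t1$nodes, t2$nodes)

  one <- generateTree(testSpec(702, treeDepth = 0L, nTrees = 1L))
  expect_equal(nrow(one$segments), 1)
  expect_equal(nrow(one$nodes), 2)
  expect_equal(sum(one$nodes$kind == "bifurcation"), 0)

  d4 <- generateTree(testSpec(703, treeDepth = 4L, nTrees = 1L))
  expect_lte(nrow(d4$segments), 2^5 - 1)
  # every bifurcation node is an internal segment endpoint
  expect_equal(sum(d4$nodes$kind == "bifurcation"),
               sum(d4$segments$to %in% d4$segments$from))
})

test_that("rendering leaves the background constant without noise or gradient", {
  spec <- testSpec(704, noiseSd = 0, illuminationAmp = 0)
  tree <- generateTree(spec)
  img <- renderPhantom(tree, spec)
  far <- pixels(img)[1:12, 1:12]          # corner away from vessels
  expect_true(all(abs(far - spec$background) < 1e-12))
})

test_that("the reflection ridge produces a min-max-min cross-section", {
  spec <- testSpec(705, noiseSd = 0, illuminationAmp = 0,
                   reflectionAmp = 0.15, treeDepth = 1L, nTrees = 1L,
                   widthRoot = 4)
  tree <- generateTree(spec)
  img <- renderPhantom(tree, spec)
  # cross-section through the root segment midpoint, normal to it
  p <- tree$segments$path[[1]]
  mid <- p[nrow(p) %/% 2, ]
  dirv <- p[nrow(p) %/% 2 + 1, ] - p[nrow(p) %/% 2 - 1, ]
  nrm <- c(-dirv[2], dirv[1]) / sqrt(sum(dirv^2))
  off <- seq(-8, 8, by = 0.5)
  prof <- fundusreg:::bilinearSample(pixels(img),
                                     mid[1] + off * nrm[1],
                                     mid[2] + off * nrm[2])
  ctr <- which.min(abs(off))
  # center brighter than the flanks of the vessel, flanks darker than bg
  flank <- c(ctr - 6, ctr + 6)
  expect_gt(prof[ctr], max(prof[flank]))
  expect_lt(min(prof[flank]), spec$background - 0.1)
})

test_that("a noiseless phantom pair maps ground-truth nodes within a pixel", {
  spec <- testSpec(706, warp = SimilarityTransform(1.1, 15 * pi / 180,
                                                   c(4, 10)))
  pair <- makePhantomPair(spec, render = FALSE)
  tc <- pair$trueCorrespondences
  expect_gt(nrow(tc), 5)
  p2 <- as.matrix(nodes(pair$graphFloat)[
    match(tc$float, nodes(pair$graphFloat)$id), c("row", "col")])
  p1 <- as.matrix(nodes(pair$graphRef)[
    match(tc$ref, nodes(pair$graphRef)$id), c("row", "col")])
  err <- sqrt(rowSums((applyTransform(pair$trueTransform, p2) - p1)^2))
  expect_lt(max(err), 1)
})

test_that("the identity warp with zero noise yields identical graphs", {
  spec <- testSpec(707)
  pair <- makePhantomPair(spec, render = FALSE)
  expect_identical(nodes(pair$graphRef), nodes(pair$graphFloat))
  expect_equal(nrow(pair$trueCorrespondences), nrow(nodes(pair$graphRef)))
})

test_that("structure noise injects the requested fraction of partnerless nodes", {
  spec <- testSpec(708, structureNoise = 0.5, treeDepth = 4L)
  pair <- makePhantomPair(spec, render = FALSE)
  nFloat <- nrow(nodes(pair$graphFloat))
  nTrue <- sum(nodes(pair$graphFloat)$id %in% pair$trueCorrespondences$float)
  expect_equal(1 - nTrue / nFloat, 0.5, tolerance = 0.15)
})

test_that("phantom pairs are bit-identical across repeated construction", {
  spec <- testSpec(709, warp = SimilarityTransform(1.05, 0.1, c(3, 6)),
                   structureNoise = 0.2)
  p1 <- makePhantomPair(spec)
  p2 <- makePhantomPair(spec)
  expect_identical(pixels(p1$imageRef), pixels(p2$imageRef))
  expect_identical(pixels(p1$imageFloat), pixels(p2$imageFloat))
  expect_identical(nodes(p1$graphFloat), nodes(p2$graphFloat))
})

test_that("overlap targeting lands near the requested percentage", {
  spec <- testSpec(710, warp = SimilarityTransform(1.05, 0.2, c(0, 0)),
                   overlapTarget = 70)
  pair <- makePhantomPair(spec, render = FALSE)
  got <- overlapPct(spec$imageShape, pair$trueTransform, spec$imageShape)
  expect_equal(got, 70, tolerance = 3)
})

test_that("extraction on noiseless phantoms recovers the true bifurcations", {
  # render -> filter -> probe -> thin -> graph; a junction counts as
  # recovered within 6 px (junction blobs displace the skeleton crossing
  # by a few pixels where response bands merge)
  recalls <- locs <- c()
  for (sd in 711:713) {
    spec <- phantomSpec(seed = sd, imageShape = c(500L, 600L),
                        rootLength = 160, treeDepth = 3L,
                        noiseSd = 0, illuminationAmp = 0)
    tree <- generateTree(spec)
    img <- renderPhantom(tree, spec)
    ex <- extractVesselGraph(img)
    gt <- treeGraph(tree, spec$imageShape)
    gtb <- as.matrix(nodes(gt)[nodes(gt)$kind == "bifurcation",
                               c("row", "col")])
    exn <- as.matrix(nodes(ex$graph)[, c("row", "col")])
    d <- sqrt(outer(gtb[, 1], exn[, 1], "-")^2 +
                outer(gtb[, 2], exn[, 2], "-")^2)
    nn <- apply(d, 1, min)
    recalls <- c(recalls, mean(nn <= 6))
    locs <- c(locs, nn[nn <= 6])
  }
  expect_gte(mean(recalls), 0.9)
  expect_lte(median(locs), 2.5)
})
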